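# Packaged example designs: a deep-mutational-scanning library for the
# GB1 domain, an MPRA regulatory-grammar library, and a cryptic
# 5' splice-site insertion library for in silico perturbation studies.

# 56-residue GB1 domain (start Met + 55 scanned residues). All library
# counts depend only on the 55 eligible positions, not on the codons; the
# coding sequence is obtained by most-frequent-codon encoding.
.GB1_PROTEIN <- "MQYKLILNGKTLKGETTTEAVDAATAEKVFKQYANDNGVDGEWTYDDATKTFTVTE"

#' Wild-type coding sequence used by the GB1 example
#'
#' @param usage Codon-usage table; default packaged human table.
#' @return Tagged text: the most-frequent-codon encoding of the 56-residue
#'   GB1 domain plus a terminal stop, wrapped in an `<orf>` region.
#' @export
gb1_orf <- function(usage = NULL) {
  paste0("<orf>", encode_peptide(paste0(.GB1_PROTEIN, "*"), usage), "</orf>")
}

#' GB1 deep-mutational-scanning library
#'
#' Four branches over one wild-type ORF pool: 100 wild-type replicates;
#' all single amino-acid substitutions of the 55 eligible residues
#' (excluding the start codon; 55 x 19 = 1,045); all pairwise
#' substitutions (choose(55,2) x 19^2 = 536,085); and `n_random` random
#' higher-order variants mutating each position with probability
#' `rate`. The branches are merged by a stack with labels
#' wt/single/double/multi, yielding 547,230 sequences at the defaults.
#'
#' @param n_random Sample count of the random branch.
#' @param rate Per-position mutation rate of the random branch.
#' @param usage Codon-usage table; default packaged human table.
#' @return The root pool.
#' @export
#' @examples
#' \donttest{pool_size(build_gb1())  # 547230}
build_gb1 <- function(n_random = 10000, rate = 0.1, usage = NULL) {
  usage <- usage %||% load_codon_usage()
  orf <- from_seq(gb1_orf(usage))
  wt <- repeat_pool(orf, 100, prefix = "rep")
  single <- mutagenize_orf(orf, "single", region = "orf", prefix = "mut",
                           usage = usage)
  double <- mutagenize_orf(orf, "pairwise", region = "orf", prefix = "mut",
                           usage = usage)
  multi <- mutagenize_orf(orf, "random", region = "orf", rate = rate,
                          n = n_random, prefix = "mut", usage = usage)
  stack_pools(wt = wt, single = single, double = double, multi = multi)
}

# Consensus-like synthetic binding-site motifs for three liver-enriched
# transcription factors (labels only; not measured genomic sites).
.TFBS_MOTIFS <- c(HNF4A = "GGGTCAAAGGTTCA",
                  PPARA = "AGGTCAAAGGTCA",
                  XBP1 = "TGACGTGG")

#' Synthetic TFBS motifs used by the MPRA example
#' @return Named character vector of consensus-like motifs.
#' @export
tfbs_motifs <- function() .TFBS_MOTIFS

# Putatively inert 100-bp CRE filler and template layout.
.MPRA_CRE <- paste0(
  "ATCGCACAGTGACTAGGTACTCGAAGTCCAGTTCAGATCC",
  "ATACGCTTGACGGATTAGCCAGTCGTTAACGCATCTGGAA",
  "TTGACCGTACAGCTTAGGCA")

mpra_template <- function(barcode_length = 10) {
  paste0("ACTGGCCGCTTCACTG", "<cre>", .MPRA_CRE, "</cre>",
         "GGTACC", "<bc>", strrep("N", barcode_length), "</bc>",
         "AGATCGGAAG")
}

#' MPRA regulatory-grammar library
#'
#' A template with a gray-shaded 100-bp CRE region and a barcode region;
#' three TFBS pools (HNF4A blue, PPARA purple, XBP1 orange), each flipped
#' to include both orientations; `n` multiscan insertions of the three
#' sites at random non-overlapping placements inside the CRE; three
#' replicates of each insertion variant; and a distinct barcode per
#' sequence. Yields `3 * n` sequences (30,000 at the default).
#'
#' @param n Multiscan sample count.
#' @param n_replicates Replicates per insertion variant.
#' @param barcode_length Barcode length (nt).
#' @return The root pool.
#' @export
#' @examples
#' \donttest{pool_size(build_mpra())  # 30000}
build_mpra <- function(n = 10000, n_replicates = 3, barcode_length = 10) {
  tmpl <- stylize(from_seq(mpra_template(barcode_length)),
                  region = "cre", bg = "gray")
  styles <- list(HNF4A = list(fg = "blue"), PPARA = list(fg = "purple"),
                 XBP1 = list(fg = "orange"))
  sites <- lapply(names(.TFBS_MOTIFS), function(nm) {
    flip(from_seqs(.TFBS_MOTIFS[[nm]], style = styles[[nm]]))
  })
  names(sites) <- names(.TFBS_MOTIFS)
  scan <- insert_multiscan(tmpl, sites, region = "cre", n = n,
                           prefix = "cre")
  reps <- repeat_pool(scan, n_replicates, prefix = "rep")
  get_barcodes(reps, region = "bc", length = barcode_length)
}

#' Human 5' splice-site position weight matrix (packaged)
#'
#' Nine positions (-3..+6 around the exon/intron boundary), columns A, C,
#' G, T; consensus CAG|GTAAGT with the GT dinucleotide invariant, as in
#' standard human donor-site models.
#'
#' @return A 9 x 4 probability matrix.
#' @export
ss5_pwm <- function() {
  path <- system.file("extdata", "ss5_pwm.tsv", package = "oligopool",
                      mustWork = TRUE)
  as.matrix(utils::read.delim(path, row.names = 1))
}

#' PWM log-odds strength scorer
#'
#' Pluggable stand-in splice-site strength scorer: the sum over positions
#' of `log2(p / background)` for the observed base.
#'
#' @param pwm Probability matrix, positions x 4 (A, C, G, T).
#' @param background Background base probability (default uniform 0.25).
#' @return `function(kmers)` returning one score per input string.
#' @export
pwm_logodds_scorer <- function(pwm, background = 0.25) {
  lo <- log2(pmax(pwm, 1e-9) / background)
  colnames(lo) <- c("A", "C", "G", "T")
  function(kmers) {
    vapply(strsplit(kmers, "", fixed = TRUE), function(ch) {
      sum(lo[cbind(seq_along(ch), match(ch, colnames(lo)))])
    }, numeric(1))
  }
}

# Synthetic exon/intron junction: 60-bp exon ending in CAG, 60-bp intron
# beginning GTAAGT; the canonical donor 9-mer occupies [57, 66).
.SPLICE_EXON <- paste0(
  "GCTACCTGGAGATCGTTCCTAAGGACGATCAGCTTGAAGTCTCCGGAACTTCTGGACCAG")
.SPLICE_INTRON <- paste0(
  "GTAAGTCCTTAGAGGCATCACGATTGCTTACCAGGATCGAAGCTTGACTCCAGGTTCATA")

splice_template <- function() {
  paste0("<tmpl>", .SPLICE_EXON, .SPLICE_INTRON, "</tmpl>")
}

#' Cryptic 5' splice-site insertion library
#'
#' Builds the perturbation library of an in silico splice-site
#' experiment: 9-mers are sampled from the packaged donor-site PWM,
#' deduplicated, scored with a pluggable strength scorer (default: PWM
#' log-odds), binned into `n_bins` equal-count score quantiles, and
#' `per_bin` sequences are drawn per bin (2,000 at the defaults). Each
#' retained 9-mer is inserted at 100 positions flanking the canonical
#' donor site of a synthetic exon/intron template - 50 exonic and 50
#' intronic offsets, never splitting the canonical 9-mer - and paired
#' with a matched control in which the GT dinucleotide is disrupted
#' (T>A at +2). Design cards record the site strength, the insertion
#' offset, and the variant/control branch.
#'
#' @param master_seed Master seed for the sampling and binning draws.
#' @param n_sample PWM sample count before deduplication.
#' @param n_bins,per_bin Quantile-binning parameters.
#' @param scorer Strength scorer `function(kmers) -> numeric`; default
#'   [pwm_logodds_scorer()] on the packaged PWM.
#' @param detail If `TRUE`, return `list(root, sites, kmers, strengths)`
#'   instead of just the root pool.
#' @return The root pool (or a detail list): cardinality
#'   `2 * 100 * n_bins * per_bin`.
#' @export
build_splice <- function(master_seed = 0, n_sample = 50000, n_bins = 100,
                         per_bin = 20, scorer = NULL, detail = FALSE) {
  pwm <- ss5_pwm()
  src <- from_pwm(pwm, n_sample, prefix = "ss")
  kmers <- vapply(seq_len(n_sample) - 1,
                  function(i) pwm_draw(src, i, master_seed), character(1))
  uniq <- unique(kmers)
  if (length(uniq) < n_bins * per_bin) {
    stop(sprintf(
      "only %d distinct 9-mers from %d draws; need >= %d - raise n_sample",
      length(uniq), n_sample, n_bins * per_bin), call. = FALSE)
  }
  scorer <- scorer %||% pwm_logodds_scorer(pwm)
  sc <- scorer(uniq)
  o <- order(sc)
  bin <- ceiling(seq_along(o) * n_bins / length(o))
  if (min(table(bin)) < per_bin) {
    stop("quantile bins too small for per_bin draws", call. = FALSE)
  }
  seed_stream(master_seed, src$id, 0, "quantile_draw")
  sel_idx <- unlist(lapply(seq_len(n_bins), function(q) {
    sample(o[bin == q], per_bin)
  }))
  sel <- uniq[sel_idx]
  strengths <- sc[sel_idx]
  sites <- from_seqs(sel, prefix = "site",
                     card_vars = data.frame(strength = round(strengths, 4)))
  controls <- edit_seq(sites, 4, 5, "A")  # +2 of the 9-mer: GT -> GA
  tmpl <- from_seq(splice_template())
  offsets <- c(8:57, 66:115)  # 50 exonic + 50 intronic insertion points
  variant <- insert_at(tmpl, sites, region = "tmpl", offsets = offsets,
                       prefix = "pos")
  control <- insert_at(tmpl, controls, region = "tmpl", offsets = offsets,
                       prefix = "pos")
  root <- stack_pools(variant = variant, control = control)
  if (detail) {
    list(root = root, sites = sites, kmers = sel, strengths = strengths)
  } else {
    root
  }
}
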