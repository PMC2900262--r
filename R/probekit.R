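#' Reverse complement of a DNA sequence
#'
#' Capture probes are DNA oligos complementary to their (RNA) targets, so
#' relating a probe to its target means reverse-complementing.  RNA input is
#' accepted: `U` is silently normalized to `T` before complementing, since
#' assays mix synthetic RNA spikes with DNA probes.
#'
#' @param seq A single DNA (or RNA) string over `A`,`C`,`G`,`T`/`U`,
#'   case-insensitive.
#' @return The reverse complement, uppercase DNA, same length as `seq`.
#' @examples
#' revcomp("TCTTAGTCTTGATTGTGGCAATG")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- normalize_dna(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  paste(rev(chartr("ACGT", "TGCA", chars)), collapse = "")
}

# uppercase, U->T, reject anything outside {A,C,G,T} reporting 1-based position
normalize_dna <- function(seq) {
  s <- chartr("u", "t", toupper(seq))
  s <- chartr("U", "T", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    stop("invalid nucleotide '", chars[bad[1]], "' at position ", bad[1])
  }
  s
}

#' Positions at which a variant probe mismatches its parent
#'
#' Equal-length Hamming comparison only (no alignment): capture-probe
#' mismatch variants are substitutions at fixed positions.  Positions are
#' 1-based on the probe sequence read 5' to 3'.
#'
#' @param parent,variant DNA sequences (strings), or single rows of a probe
#'   table (any list/data.frame carrying a `sequence` element).
#' @return Integer vector of 1-based mismatch positions, ascending; empty
#'   when the sequences are identical.
#' @examples
#' mismatch_positions("GCGGAACTTAGCCACTGTGAA", "GCGGAACTAAGCCACTGTGAA")
#' @export
mismatch_positions <- function(parent, variant) {
  p <- normalize_dna(extract_sequence(parent))
  v <- normalize_dna(extract_sequence(variant))
  if (nchar(p) != nchar(v)) {
    stop("sequences have unequal lengths (", nchar(p), " vs ", nchar(v),
         "); no alignment is attempted")
  }
  pc <- strsplit(p, "", fixed = TRUE)[[1]]
  vc <- strsplit(v, "", fixed = TRUE)[[1]]
  which(pc != vc)
}

extract_sequence <- function(x) {
  if (is.character(x) && length(x) == 1L) return(x)
  if (!is.null(x$sequence)) return(as.character(x$sequence)[1])
  stop("expected a sequence string or a record with a 'sequence' field")
}

#' Labeling scheme for small-RNA amplification (mRAP-style)
#'
#' The labeling reaction polyadenylates small RNAs, reverse-transcribes with
#' an oligo-dT primer carrying a T7-containing overhang, and appends a
#' template-switch (SMART) adaptor at the 5' end; degenerate oligo-dT caps
#' the poly(A) tract at 15 nt.  Defaults are the published primer/adaptor
#' sequences.
#'
#' @param smart_adaptor 5' template-switch adaptor sequence (36 nt default).
#' @param rt_primer_overhang Overhang of the oligo-dT15-T7 RT primer
#'   (31 nt default, excludes the dT15 tract itself).
#' @param polyA_len Length of the poly(A) tract retained in the cDNA (nt).
#' @return A `labeling_scheme` list.
#' @export
labeling_scheme <- function(
    smart_adaptor = "TACAAAAAAGCAGGCTAATTAACCCTCACTAAAGGG",
    rt_primer_overhang = "GTGAATTGTTAATACGACTCACTATAGGCGC",
    polyA_len = 15L) {
  smart_adaptor <- normalize_dna(smart_adaptor)
  rt_primer_overhang <- normalize_dna(rt_primer_overhang)
  stopifnot(is.numeric(polyA_len), length(polyA_len) == 1L, polyA_len >= 0)
  structure(
    list(smart_adaptor = smart_adaptor,
         rt_primer_overhang = rt_primer_overhang,
         polyA_len = as.integer(polyA_len)),
    class = "labeling_scheme")
}

#' Length of the labeled cDNA for a miRNA of given length
#'
#' adaptor + miRNA + poly(A) + RT-primer overhang.  With the default scheme a
#' mature miRNA of 18-24 nt yields a 100-110 nt labeled cDNA.
#'
#' @param mirna_len Mature miRNA length in nt (15-30 accepted).
#' @param scheme A [labeling_scheme()].
#' @return Integer cDNA length in nt.
#' @examples
#' labeled_cdna_length(22)
#' @export
labeled_cdna_length <- function(mirna_len, scheme = labeling_scheme()) {
  stopifnot(inherits(scheme, "labeling_scheme"))
  if (!is.numeric(mirna_len) || length(mirna_len) != 1L ||
      mirna_len < 15 || mirna_len > 30) {
    stop("mirna_len must be a single value in [15, 30]")
  }
  as.integer(nchar(scheme$smart_adaptor) + mirna_len +
               scheme$polyA_len + nchar(scheme$rt_primer_overhang))
}

#' Built-in capture-probe table
#'
#' The packaged capture-probe set: perfect-match probes for miR-23a, miR-27a
#' and miR-199a, their one- and two-mismatch variants, and the Spike-18
#' pre-labeling control probe.  Bead-region codes are assigned to the four
#' probes hybridized together in expression wells; mismatch variants take
#' their region per experiment.
#'
#' @return A data.frame of probe records (id, sequence, length_nt,
#'   parent_id, mismatch_count, bead_region).
#' @export
capture_probes <- function() {
  path <- system.file("extdata", "capture_probes_table1.tsv",
                      package = "beadmiR", mustWork = TRUE)
  read_probe_table(path)
}
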