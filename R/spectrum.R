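#' Canonical SBS-96 channel labels
#'
#' The 96 single-base-substitution classes: six pyrimidine-strand
#' substitutions (C>A, C>G, C>T, T>A, T>C, T>G) times the 4 x 4 flanking
#' bases, labelled like `"A[C>A]A"`. Ordering is substitution-major, the
#' layout used by COSMIC signature tables; all joins elsewhere are by
#' label, so only the set matters.
#'
#' @return character vector of length 96.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(l, r)
      paste0(l, "[", s, "]", r))))
  }))
}

# reverse complement of a character vector of DNA strings
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Classify single-base substitutions into SBS-96 channels
#'
#' Looks up the trinucleotide context of each substitution in the
#' reference and assigns the pyrimidine-strand channel label. Records
#' whose reference base is a purine (A or G) are reverse-complemented —
#' ref, alt and both flanks — before labelling, so `T·G·A, G>T` becomes
#' `"T[C>A]A"`. A mismatch between the record's REF and the reference
#' sequence is an error; a flank containing N yields `NA` (the caller
#' counts and skips such records).
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`
#'   (single-base substitutions).
#' @param reference a named `Biostrings::DNAStringSet` (names matching
#'   `chrom`) or path to a FASTA file.
#' @return character vector of channel labels (NA where a flank is
#'   unavailable or ambiguous).
#' @export
classify_sbs96 <- function(variants, reference) {
  if (is.character(reference) && length(reference) == 1) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  bad_base <- !(variants$ref %in% c("A", "C", "G", "T")) |
    !(variants$alt %in% c("A", "C", "G", "T"))
  if (any(bad_base)) stop("classify_sbs96 handles single-base A/C/G/T substitutions only")
  seqs <- lapply(reference, as.character)
  out <- rep(NA_character_, nrow(variants))
  for (chr in unique(variants$chrom)) {
    if (!chr %in% names(seqs)) stop("contig absent from reference: ", chr)
    s <- seqs[[chr]]
    i <- which(variants$chrom == chr)
    pos <- variants$pos[i]
    if (any(pos < 1 | pos > nchar(s))) stop("position outside reference on ", chr)
    mid <- substring(s, pos, pos)
    mism <- mid != variants$ref[i]
    if (any(mism)) {
      stop(sprintf("REF mismatch at %s:%d (file %s, reference %s)",
                   chr, pos[which(mism)[1]],
                   variants$ref[i][which(mism)[1]], mid[which(mism)[1]]))
    }
    tri <- substring(s, pmax(pos - 1, 1), pos + 1)
    ok <- pos > 1 & pos < nchar(s) & !grepl("[^ACGT]", tri)
    ref <- variants$ref[i]
    alt <- variants$alt[i]
    flip <- ref %in% c("A", "G")
    tri[flip & ok] <- revcomp(tri[flip & ok])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    lab <- paste0(substr(tri, 1, 1), "[", substr(tri, 2, 2), ">", alt, "]",
                  substr(tri, 3, 3))
    out[i] <- ifelse(ok, lab, NA_character_)
  }
  out
}

#' Build an SBS-96 mutation spectrum from variant records
#'
#' Counts nonsynonymous single-base substitutions per sample and
#' channel. Only records flagged `is_nonsynonymous` are counted; the
#' spectrum therefore matches a TMB computed from amino-acid-changing
#' mutations. Records whose context cannot be resolved (flanking N or
#' sequence edge) are skipped with a logged count. Samples named in
#' `samples` but absent from `variants` are retained as all-zero rows.
#'
#' @param variants variant data.frame (see [read_variants()]).
#' @param reference named `DNAStringSet` or FASTA path.
#' @param samples optional character vector fixing the row set/order;
#'   defaults to the samples present in `variants`.
#' @return integer matrix, samples x 96 channels, with a
#'   `channel_system` attribute of `"SBS-96"`.
#' @export
build_spectrum <- function(variants, reference, samples = NULL) {
  channels <- sbs96_channels()
  if (is.null(samples)) samples <- unique(variants$sample_id)
  X <- matrix(0L, nrow = length(samples), ncol = length(channels),
              dimnames = list(samples, channels))
  v <- variants[variants$is_nonsynonymous, , drop = FALSE]
  if (nrow(v) > 0) {
    lab <- classify_sbs96(v, reference)
    skipped <- sum(is.na(lab))
    if (skipped > 0) sb_log(skipped, " record(s) skipped: unresolvable context",
                            level = "WARN")
    keep <- !is.na(lab)
    tab <- table(factor(v$sample_id[keep], levels = samples),
                 factor(lab[keep], levels = channels))
    X[] <- as.integer(tab)
  }
  zero <- rowSums(X) == 0
  if (any(zero)) sb_log("all-zero spectrum row(s): ",
                        paste(samples[zero], collapse = ", "), level = "WARN")
  attr(X, "channel_system") <- "SBS-96"
  X
}
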