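#' Derive the durable-benefit label from follow-up
#'
#' Durable benefit (DB) is progression-free survival of at least half a
#' year. PFS is recorded in weeks, so the cutoff is 26 weeks exactly.
#' A patient is `"yes"` when PFS reaches the cutoff (whether or not an
#' event was observed afterwards), `"no"` when progression or death was
#' observed before the cutoff, and `"unknown"` when follow-up was
#' censored before the cutoff so the label cannot be assigned.
#'
#' @param pfs_weeks non-negative numeric vector of PFS in weeks.
#' @param event logical vector; `TRUE` when progression/death was observed.
#' @param cutoff_weeks DB cutoff in weeks (default 26, i.e. half a year).
#' @return character vector in `c("yes", "no", "unknown")`.
#' @export
derive_db_label <- function(pfs_weeks, event, cutoff_weeks = 26) {
  stopifnot(length(pfs_weeks) == length(event))
  if (any(pfs_weeks < 0, na.rm = TRUE)) stop("pfs_weeks must be non-negative")
  event <- as.logical(event)
  ifelse(pfs_weeks >= cutoff_weeks, "yes",
         ifelse(event, "no", "unknown"))
}

#' Read somatic variant calls from a VCF file
#'
#' Parses a VCF 4.x file into a flat variant table. Multi-allelic
#' records are split into one row per ALT allele; records whose FILTER
#' column is neither `PASS` nor missing (`.`) are excluded, so only
#' curated somatic calls enter downstream spectra. The nonsynonymous
#' status is taken from the input annotation: only records carrying the
#' INFO flag `NONSYN` are marked amino-acid-changing (and later counted
#' into spectra and TMB). An optional `GENE=` INFO key populates the
#' gene column.
#'
#' @param path path to a VCF file.
#' @param sample_id sample identifier attached to every record.
#' @return data.frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `is_nonsynonymous`, `gene`.
#' @export
read_variants <- function(path, sample_id) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      is_nonsynonymous = logical(), gene = character(),
                      stringsAsFactors = FALSE))
  }
  keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  fix <- fix[keep, , drop = FALSE]
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  info <- fix$INFO[idx]
  info[is.na(info)] <- "."
  nonsyn <- grepl("(^|;)NONSYN($|;|=)", info)
  gene <- rep(NA_character_, length(idx))
  gm <- regmatches(info, regexpr("(?<=(^|;)GENE=)[^;]+", info, perl = TRUE))
  gene[grepl("(^|;)GENE=", info)] <- gm
  out <- data.frame(
    sample_id = sample_id,
    chrom = fix$CHROM[idx],
    pos = as.integer(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = unlist(alt_list),
    is_nonsynonymous = nonsyn,
    gene = gene,
    stringsAsFactors = FALSE
  )
  bad <- out$ref == out$alt
  if (any(bad)) stop("record with REF == ALT at row ", which(bad)[1])
  out
}

#' Read a fixed signature catalog (COSMIC-style TSV)
#'
#' The file holds one row per mutation channel with a `Type` label
#' column (e.g. `"A[C>A]A"`) and one column per signature, as COSMIC
#' distributes its catalogs. The returned catalog stores the transposed
#' signatures-by-channels probability matrix `H`. Each signature is
#' renormalised to sum to exactly 1 when its column sum is within 1e-3
#' of 1, and rejected otherwise. Because channel order varies between
#' catalog releases, all downstream algebra joins on channel labels,
#' never on column position.
#'
#' @param path path to the TSV catalog.
#' @param artefacts character vector of signature names flagged as
#'   possible sequencing artefacts (excluded later by
#'   [filter_signatures()]).
#' @return an object of class `signature_catalog`: a list with `H`
#'   (p x n matrix, rows sum to 1) and `artefact` (named logical).
#' @export
read_signature_catalog <- function(path, artefacts = character()) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  label_col <- if ("Type" %in% names(tab)) "Type" else names(tab)[1]
  channels <- as.character(tab[[label_col]])
  mat <- as.matrix(tab[, setdiff(names(tab), label_col), drop = FALSE])
  storage.mode(mat) <- "double"
  H <- t(mat)                               # signatures x channels
  colnames(H) <- channels
  signature_catalog(H, artefacts = artefacts)
}

#' Construct and validate a signature catalog
#'
#' @param H numeric matrix, signatures (rows) by channels (columns);
#'   rows must sum to 1 within 1e-3 and are renormalised exactly.
#' @param artefacts names of artefact-flagged signatures.
#' @return `signature_catalog` object.
#' @export
signature_catalog <- function(H, artefacts = character()) {
  if (is.null(rownames(H)) || is.null(colnames(H))) {
    stop("catalog matrix needs signature rownames and channel colnames")
  }
  if (anyDuplicated(colnames(H))) stop("duplicate channel labels")
  if (any(H < 0)) stop("negative entry in signature catalog")
  if (ncol(H) == 96 && !all(colnames(H) %in% sbs96_channels())) {
    stop("unknown channel label in 96-channel catalog: ",
         setdiff(colnames(H), sbs96_channels())[1])
  }
  rs <- rowSums(H)
  if (any(abs(rs - 1) > 1e-3)) {
    stop("signature row(s) do not sum to 1 within 1e-3: ",
         paste(rownames(H)[abs(rs - 1) > 1e-3], collapse = ", "))
  }
  H <- H / rs
  artefact <- stats::setNames(rownames(H) %in% artefacts, rownames(H))
  structure(list(H = H, artefact = artefact), class = "signature_catalog")
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat(sprintf("signature_catalog: %d signatures x %d channels (%d artefact-flagged)\n",
              nrow(x$H), ncol(x$H), sum(x$artefact)))
  invisible(x)
}

#' Read a clinical cohort table
#'
#' Expects a CSV with columns `sample_id`, `pfs_weeks`, `event` and any
#' optional covariates (`prior_therapy`, `smoking`, `purity`, `age`,
#' `cohort`). The durable-benefit label is always re-derived from
#' (`pfs_weeks`, `event`) via [derive_db_label()]; a `db_label` column
#' present in the file is ignored. Records with missing PFS are dropped
#' with a warning.
#'
#' @param path CSV path.
#' @param cutoff_weeks DB cutoff passed to [derive_db_label()].
#' @return data.frame with a derived `db_label` column.
#' @export
read_cohort <- function(path, cutoff_weeks = 26) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "pfs_weeks", "event")
  if (!all(need %in% names(tab))) {
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  }
  miss <- is.na(tab$pfs_weeks)
  if (any(miss)) {
    warning(sum(miss), " record(s) rejected: missing pfs_weeks")
    tab <- tab[!miss, , drop = FALSE]
  }
  tab$event <- as.logical(tab$event)
  tab$db_label <- derive_db_label(tab$pfs_weeks, tab$event, cutoff_weeks)
  tab
}

#' Write a labelled numeric matrix as TSV
#'
#' Row names go into a leading `id` column; values are written with
#' full precision so a write/read round trip reproduces them to at
#' least 12 significant digits.
#'
#' @param path output path.
#' @param m numeric matrix with row and column names.
#' @export
write_matrix <- function(path, m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled numeric matrix from TSV
#'
#' Inverse of [write_matrix()]: first column holds row ids.
#'
#' @param path TSV path.
#' @return numeric matrix.
#' @export
read_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  m
}

#' Read a precomputed mutation spectrum
#'
#' Samples as rows, labelled mutation channels as columns. Used for
#' channel systems whose extraction is not native here (DBS-78, ID-83,
#' CN-48) and for cached SBS-96 spectra.
#'
#' @param path TSV path (layout of [write_matrix()]).
#' @param system optional channel-system tag; when given, the column
#'   count must match (SBS-96: 96, DBS-78: 78, ID-83: 83, CN-48: 48).
#' @return non-negative numeric matrix with a `channel_system` attribute.
#' @export
read_spectrum <- function(path, system = NULL) {
  m <- read_matrix(path)
  if (any(m < 0)) stop("negative count in spectrum")
  if (!is.null(system)) {
    n_expect <- c("SBS-96" = 96L, "DBS-78" = 78L, "ID-83" = 83L, "CN-48" = 48L)[system]
    if (is.na(n_expect)) stop("unknown channel system: ", system)
    if (ncol(m) != n_expect) {
      stop(sprintf("%s spectrum must have %d channels, found %d",
                   system, n_expect, ncol(m)))
    }
    attr(m, "channel_system") <- system
  }
  m
}
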