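# Reading and writing variant tables (supplementary-file CSV dialect)
# and aligned-FASTA multiple sequence alignments.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default column mapping for variant tables
#'
#' The shipped mapping follows the narrative order of the supplementary
#' variant files: the amino-acid replacement token, the UniProt
#' accession, the three biological features, the outputs of the
#' reference predictors (both PolyPhen-2 versions are carried; only
#' HDIV feeds the analysis) and the dataset tag.  A trailing `label`
#' column is written/read when present so that tables round-trip; the
#' supplementary files themselves carry the label implicitly (one file
#' per class), which the `label` argument of [read_variant_table()]
#' covers.
#'
#' @param sep Field separator; `NULL` auto-detects among comma,
#'   semicolon and tab.
#' @return A dialect description (list) understood by
#'   [read_variant_table()] and [write_variant_table()].
#' @export
default_dialect <- function(sep = NULL) {
  list(
    sep = sep,
    replacement = "replacement",  # single token, e.g. "A42V"
    native = NULL, position = NULL, variant = NULL,  # alternative 3-column form
    protein = "protein",
    features = c(blosum62 = "blosum62", pssm_nat = "pssm_nat",
                 entropy = "entropy"),
    predictors = c(SIFT = "SIFT", PolyPhen2 = "PolyPhen2_HDIV",
                   PolyPhen2_HVAR = "PolyPhen2_HVAR", PONP2 = "PONP2",
                   CADD = "CADD", MutationTaster2 = "MutationTaster2"),
    dataset_tag = "dataset",
    label = "label")
}

#' Read a column-mapping dialect from a YAML file
#'
#' Fields absent from the file keep their [default_dialect()] values.
#'
#' @param path YAML file path.
#' @return A dialect list.
#' @export
read_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  d <- default_dialect()
  for (nm in names(cfg)) {
    d[[nm]] <- if (nm %in% c("features", "predictors")) unlist(cfg[[nm]]) else cfg[[nm]]
  }
  d
}

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- vapply(c(",", ";", "\t"),
                   function(s) lengths(regmatches(header, gregexpr(s, header, fixed = TRUE))),
                   integer(1))
  if (all(counts == 0)) "," else names(counts)[which.max(counts)]
}

.parse_replacement <- function(tokens) {
  m <- regmatches(tokens, regexec("^\\s*([A-Za-z])(\\d+)([A-Za-z])\\s*$", tokens))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed replacement token in data row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), ": ",
         paste(utils::head(tokens[bad], 5), collapse = ", "))
  }
  data.frame(
    native_aa = toupper(vapply(m, `[`, character(1), 2)),
    position = as.integer(vapply(m, `[`, character(1), 3)),
    variant_aa = toupper(vapply(m, `[`, character(1), 4)),
    stringsAsFactors = FALSE)
}

#' Read a variant table
#'
#' Parses a delimited text file of variants into the canonical variant
#' table layout.  `'?'` (and empty) cells become missing values; the
#' replacement column is parsed into native residue, position and
#' variant residue.  Raw predictor outputs are kept verbatim as
#' character columns — numeric scores and categorical calls alike —
#' and are only binarised downstream.
#'
#' @param path File to read.
#' @param dialect Column mapping, see [default_dialect()].
#' @param label Class label to assign to every row (for files that are
#'   one-per-class); `NULL` uses the file's label column when mapped,
#'   else `"unlabeled"`.
#' @return A variant table.
#' @export
read_variant_table <- function(path, dialect = default_dialect(), label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- dialect$sep %||% .detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = character(0))
  raw[] <- lapply(raw, function(x) {
    x[trimws(x) %in% c("?", "")] <- NA_character_
    x
  })

  need <- function(col, what) {
    if (!is.null(col) && !col %in% names(raw)) {
      stop("dialect names ", what, " column '", col, "' absent from file")
    }
    col
  }
  for (i in seq_along(dialect$predictors)) {
    need(dialect$predictors[[i]], paste0("predictor '", names(dialect$predictors)[i], "'"))
  }

  n <- nrow(raw)
  if (n == 0) {
    return(empty_variant_table(names(dialect$predictors)))
  }
  if (!is.null(dialect$replacement)) {
    need(dialect$replacement, "replacement")
    core <- .parse_replacement(raw[[dialect$replacement]])
  } else {
    core <- data.frame(
      native_aa = toupper(raw[[need(dialect$native, "native")]]),
      position = as.integer(raw[[need(dialect$position, "position")]]),
      variant_aa = toupper(raw[[need(dialect$variant, "variant")]]),
      stringsAsFactors = FALSE)
  }

  get_num <- function(col) {
    if (is.null(col) || !col %in% names(raw)) return(rep(NA_real_, n))
    suppressWarnings(as.numeric(raw[[col]]))
  }
  lab <- if (!is.null(label)) {
    rep_len(as.character(label), n)
  } else if (!is.null(dialect$label) && dialect$label %in% names(raw)) {
    ifelse(is.na(raw[[dialect$label]]), "unlabeled", raw[[dialect$label]])
  } else {
    rep("unlabeled", n)
  }
  tag <- if (!is.null(dialect$dataset_tag) && dialect$dataset_tag %in% names(raw)) {
    ifelse(is.na(raw[[dialect$dataset_tag]]), "other", raw[[dialect$dataset_tag]])
  } else {
    rep("other", n)
  }

  df <- data.frame(
    protein_id = raw[[need(dialect$protein, "protein")]],
    core,
    label = lab,
    blosum62 = get_num(dialect$features[["blosum62"]]),
    pssm_nat = get_num(dialect$features[["pssm_nat"]]),
    entropy = get_num(dialect$features[["entropy"]]),
    dataset_tag = tag,
    stringsAsFactors = FALSE)
  for (p in names(dialect$predictors)) {
    col <- dialect$predictors[[p]]
    df[[p]] <- if (col %in% names(raw)) raw[[col]] else NA_character_
  }
  validate_variant_table(df)
}

#' Write a variant table
#'
#' Inverse of [read_variant_table()] under the same dialect: missing
#' cells are rendered as `'?'` and the substitution is emitted as a
#' replacement token (or three columns, per the dialect).
#'
#' @param records A variant table.
#' @param path Output file.
#' @param dialect Column mapping, see [default_dialect()].
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(records, path, dialect = default_dialect()) {
  validate_variant_table(records)
  sep <- dialect$sep %||% ","
  out <- data.frame(row.names = seq_len(nrow(records)))
  if (!is.null(dialect$replacement)) {
    out[[dialect$replacement]] <- paste0(records$native_aa, records$position,
                                         records$variant_aa)
  } else {
    out[[dialect$native]] <- records$native_aa
    out[[dialect$position]] <- records$position
    out[[dialect$variant]] <- records$variant_aa
  }
  out[[dialect$protein]] <- records$protein_id
  for (f in names(dialect$features)) out[[dialect$features[[f]]]] <- records[[f]]
  for (p in names(dialect$predictors)) {
    out[[dialect$predictors[[p]]]] <-
      if (p %in% names(records)) records[[p]]
      else rep(NA_character_, nrow(records))
  }
  if (!is.null(dialect$dataset_tag)) out[[dialect$dataset_tag]] <- records$dataset_tag
  if (!is.null(dialect$label)) out[[dialect$label]] <- records$label
  if (nrow(records) == 0) {
    # header-only file
    writeLines(paste(names(out), collapse = sep), path)
    return(invisible(path))
  }
  out[] <- lapply(out, function(x) ifelse(is.na(x), "?", as.character(x)))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Multiple sequence alignments

#' Construct an alignment object
#'
#' Residues are upper-cased and `.` gap characters normalised to `-`.
#'
#' @param ids Sequence identifiers (unique).
#' @param seqs Aligned residue strings, all the same length.
#' @param human_index Index of the human reference sequence.
#' @return An object of class `"msa"`.
#' @export
msa <- function(ids, seqs, human_index = 1L) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  w <- nchar(seqs)
  if (length(unique(w)) > 1) {
    stop("ragged alignment: sequence lengths ",
         paste(unique(w), collapse = ", "))
  }
  human_index <- as.integer(human_index)
  if (human_index < 1L || human_index > length(seqs)) {
    stop("human_index out of range")
  }
  structure(list(ids = ids, seqs = seqs, human_index = human_index),
            class = "msa")
}

#' Read an aligned FASTA file
#'
#' @param path Aligned FASTA file; all records must have equal aligned
#'   length.
#' @param human Identifier (or index) of the human reference sequence;
#'   defaults to the first record.
#' @return An object of class `"msa"`.
#' @export
read_msa <- function(path, human = NULL) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  idx <- 1L
  if (is.numeric(human)) {
    idx <- as.integer(human)
  } else if (is.character(human)) {
    idx <- match(human, ids)
    if (is.na(idx)) stop("human reference '", human, "' not found in ", path)
  }
  msa(ids, unname(seqs), idx)
}

#' @export
print.msa <- function(x, ...) {
  cat("MSA: ", length(x$seqs), " sequences x ", nchar(x$seqs[1]),
      " columns (human: ", x$ids[x$human_index], ")\n", sep = "")
  invisible(x)
}

# character matrix view, rows = sequences
msa_matrix <- function(m) {
  do.call(rbind, strsplit(m$seqs, "", fixed = TRUE))
}

# alignment column index for each ungapped human position
human_column_map <- function(m) {
  which(strsplit(m$seqs[m$human_index], "", fixed = TRUE)[[1]] != "-")
}

# ungapped human sequence
human_sequence <- function(m) {
  gsub("-", "", m$seqs[m$human_index], fixed = TRUE)
}
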