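# Readers and writers for molecule tables (.smi, CSV, SDF), assay CSVs and
# feature matrices. Malformed rows are collected into a rejects attribute,
# never silently dropped.

#' Read a molecule table
#'
#' Supported formats: `csv` (columns `id`, `smiles`, optional `label`),
#' `smi` (whitespace-separated SMILES and optional id; missing ids are
#' auto-assigned from the row index), `sdf` (first title line as id).
#' All structures are canonicalized; rows that fail to parse are returned
#' in the `rejects` attribute with a reason.
#'
#' @param path input file.
#' @param format `"csv"`, `"smi"` or `"sdf"`; inferred from the file
#'   extension when missing.
#' @return molecule records; attribute `rejects` is a data.frame of
#'   rejected inputs.
#' @export
read_molecule_table <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("csv", "smi", "sdf"))
  raw <- switch(format,
    csv = {
      df <- read.csv(path, stringsAsFactors = FALSE)
      stopifnot(all(c("id", "smiles") %in% names(df)))
      if (is.null(df$label)) df$label <- NA_integer_
      df[, c("id", "smiles", "label")]
    },
    smi = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      parts <- strsplit(trimws(lines), "[ \t]+")
      data.frame(
        id = vapply(seq_along(parts), function(i)
          if (length(parts[[i]]) >= 2) parts[[i]][2] else
            sprintf("mol_%d", i), character(1)),
        smiles = vapply(parts, `[[`, character(1), 1),
        label = NA_integer_, stringsAsFactors = FALSE)
    },
    sdf = .read_sdf_table(path))
  can <- suppressWarnings(canonicalize_smiles(raw$smiles))
  ok <- !is.na(can)
  rec <- data.frame(id = raw$id[ok], smiles = can[ok],
                    label = as.integer(raw$label[ok]),
                    provenance = "library", parent_id = NA_character_,
                    stringsAsFactors = FALSE)
  rejects <- data.frame(id = raw$id[!ok], input = raw$smiles[!ok],
                        reason = rep_len("unparseable structure", sum(!ok)),
                        stringsAsFactors = FALSE)
  if (!is.null(attr(raw, "rejects")))
    rejects <- rbind(rejects, attr(raw, "rejects"))
  rownames(rec) <- NULL
  attr(rec, "rejects") <- rejects
  rec
}

# SDF -> id/smiles/label data.frame; invalid entries land in rejects.
# Entries are split on "$$$$" and converted one at a time so one corrupt
# record cannot take the rest of the file down with it.
.read_sdf_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, head(ends, -1) + 1L)
  n <- length(ends)
  ids <- character(n)
  smiles <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    block <- lines[starts[i]:ends[i]]
    title <- trimws(block[1])
    ids[i] <- if (nzchar(title)) title else sprintf("mol_%d", i)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat(
        "SDF", "CAN", paste(c(block, ""), collapse = "\n"))),
      error = function(e) "")
    smi <- strsplit(trimws(out), "[\t\n]")[[1]][1]
    if (!is.na(smi) && nzchar(smi)) smiles[i] <- smi
  }
  ok <- !is.na(smiles)
  out <- data.frame(id = ids[ok], smiles = smiles[ok], label = NA_integer_,
                    stringsAsFactors = FALSE)
  attr(out, "rejects") <- data.frame(
    id = ids[!ok], input = rep_len("<corrupt SDF entry>", sum(!ok)),
    reason = rep_len("invalid SDF record", sum(!ok)),
    stringsAsFactors = FALSE)
  out
}

#' Write molecule records to CSV
#'
#' @param records molecule records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_molecule_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an assay CSV
#'
#' Expected columns: `compound`, `form`, `concentration_uM`, `replicate`,
#' `rate`, `control_flag` (and optionally `batch`).
#'
#' @param path CSV path.
#' @return assay data.frame.
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "concentration_uM", "replicate", "rate",
            "control_flag")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("assay table missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write a feature matrix with a JSON sidecar
#'
#' The CSV holds the numeric matrix (row names = molecule ids); the
#' sidecar `<path>.json` records the scaler parameters and featurization
#' config needed to reproduce the columns.
#'
#' @param feat result of [featurize()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(feat, path) {
  write.csv(data.frame(id = rownames(feat$features), feat$features,
                       check.names = FALSE),
            path, row.names = FALSE)
  sidecar <- list(scaler = list(mean = as.list(feat$scaler$mean),
                                sd = as.list(feat$scaler$sd)),
                  config = unclass(feat$config))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
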