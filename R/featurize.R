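# Featurization: concatenated ECFP (radius 2) bits + MACCS structural keys
# + 7 Z-scored physicochemical properties. The fingerprint blocks stay
# binary; only the property block is scaled.

#' Default featurization configuration
#'
#' @param ecfp_bits folded length of the extended-connectivity fingerprint
#'   (radius 2). Default 2048.
#' @param maccs_keys number of MACCS structural keys retained. Default 166
#'   (the standard key set).
#' @return a list of class `feat_config`.
#' @export
feat_config <- function(ecfp_bits = 2048L, maccs_keys = 166L) {
  stopifnot(ecfp_bits >= 64, maccs_keys >= 1, maccs_keys <= 256)
  structure(list(ecfp_bits = as.integer(ecfp_bits),
                 maccs_keys = as.integer(maccs_keys),
                 dialect = "openbabel-can"),
            class = "feat_config")
}

#' Featurize molecules for classification
#'
#' Computes the concatenated feature matrix: ECFP bits (radius 2, folded to
#' `config$ecfp_bits`), MACCS keys, and the seven physicochemical properties
#' Z-scored with a scaler fitted on a training set. When `scaler` is `NULL`
#' the input is treated as a training set and the scaler is fitted;
#' otherwise the supplied scaler is applied as-is (the test-set / library
#' pathway).
#'
#' @param mols a `data.frame` with a `smiles` column of canonical SMILES,
#'   or a character vector of canonical SMILES.
#' @param scaler a `scaler_params` object, or `NULL` to fit one.
#' @param config a [feat_config()].
#' @return list with elements `features` (numeric matrix, one row per
#'   molecule, named columns), `scaler` (`scaler_params`), `config`, and
#'   `properties` (the unscaled property data.frame).
#' @export
featurize <- function(mols, scaler = NULL, config = feat_config()) {
  smiles <- if (is.data.frame(mols)) mols$smiles else mols
  if (length(smiles) == 0) stop("featurize: empty molecule set")
  if (anyNA(smiles)) stop("featurize: NA SMILES in input")

  ecfp <- ecfp_fingerprint(smiles, nbits = config$ecfp_bits)
  maccs <- .ob_fingerprint(smiles, "MACCS")[, seq_len(config$maccs_keys),
                                            drop = FALSE]
  props <- compute_properties(smiles)

  if (is.null(scaler)) scaler <- fit_scaler(props)
  scaled <- apply_scaler(props, scaler)

  colnames(ecfp) <- paste0("ecfp_", seq_len(ncol(ecfp)))
  colnames(maccs) <- paste0("maccs_", seq_len(ncol(maccs)))
  colnames(scaled) <- paste0("prop_", .property_names)
  feats <- cbind(ecfp, maccs, scaled)
  rownames(feats) <- if (is.data.frame(mols) && !is.null(mols$id))
    mols$id else NULL
  list(features = feats, scaler = scaler, config = config,
       properties = props)
}

#' Fit a Z-score scaler on a property table
#'
#' Per-column mean and standard deviation. Columns with zero spread are
#' flagged; [apply_scaler()] maps them to 0 with a warning.
#'
#' @param props data.frame of numeric property columns.
#' @return object of class `scaler_params`.
#' @export
fit_scaler <- function(props) {
  stopifnot(is.data.frame(props), nrow(props) >= 1)
  mu <- vapply(props, mean, numeric(1))
  sigma <- vapply(props, function(x) stats::sd(x), numeric(1))
  if (nrow(props) == 1) sigma[] <- 0
  structure(list(mean = mu, sd = sigma, columns = names(props)),
            class = "scaler_params")
}

#' Apply a fitted Z-score scaler
#'
#' @param props data.frame with the scaler's columns.
#' @param scaler a `scaler_params` from [fit_scaler()].
#' @return numeric matrix of Z-scored values; zero-spread columns are
#'   scaled to 0 (with a warning).
#' @export
apply_scaler <- function(props, scaler) {
  stopifnot(inherits(scaler, "scaler_params"),
            all(scaler$columns %in% names(props)))
  x <- as.matrix(props[, scaler$columns, drop = FALSE])
  degenerate <- scaler$sd == 0
  if (any(degenerate)) {
    warning("zero-spread property column(s) scaled to 0: ",
            paste(scaler$columns[degenerate], collapse = ", "),
            call. = FALSE)
  }
  sdv <- ifelse(degenerate, Inf, scaler$sd)
  sweep(sweep(x, 2, scaler$mean, "-"), 2, sdv, "/")
}

#' Pairwise Tanimoto similarity of binary fingerprints
#'
#' @param fp binary matrix, one fingerprint per row.
#' @param fp2 optional second matrix; default compares `fp` with itself.
#' @return similarity matrix in `[0, 1]`. Two all-zero fingerprints have
#'   similarity 0 by convention.
#' @export
tanimoto <- function(fp, fp2 = fp) {
  a <- rowSums(fp)
  b <- rowSums(fp2)
  ab <- tcrossprod(fp, fp2)
  denom <- outer(a, b, "+") - ab
  sim <- ifelse(denom == 0, 0, ab / denom)
  sim
}
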