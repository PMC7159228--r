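#' Read a compound descriptor table
#'
#' Expects a CSV whose first column, `compound_id`, identifies compounds and
#' whose remaining columns are numeric molecular descriptors (the role the
#' 818-descriptor physicochemical/structural panel plays in DILI modeling).
#' Non-numeric cells are masked as missing with a logged count; duplicate
#' compound ids are a format error.
#'
#' @param path CSV path.
#' @return numeric matrix, rows = compounds (rownames = ids), columns =
#'   descriptors; missing values are `NA`.
#' @export
read_descriptor_table <- function(path) {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (!"compound_id" %in% names(raw))
    stop("descriptor table needs a compound_id column")
  if (anyDuplicated(raw$compound_id))
    stop("duplicate compound ids in descriptor table")
  ids <- raw$compound_id
  vals <- raw[setdiff(names(raw), "compound_id")]
  if (anyDuplicated(names(vals))) stop("duplicate descriptor names")
  x <- suppressWarnings(
    vapply(vals, function(col) as.numeric(col), numeric(nrow(raw))))
  x <- matrix(x, nrow = nrow(raw),
              dimnames = list(ids, names(vals)))
  n_masked <- sum(is.na(x) & !(toupper(as.matrix(vals)) %in% c("NA", "")))
  n_na <- sum(is.na(x))
  if (n_na > 0)
    message("read_descriptor_table: ", n_na, " cell(s) masked as missing",
            if (n_masked > 0) paste0(" (", n_masked, " non-numeric)") else "")
  x
}

# ---- pluggable descriptor backends -----------------------------------------

descriptor_backends <- new.env(parent = emptyenv())

#' Register a descriptor-computation backend
#'
#' A backend is a function `f(smiles)` returning a numeric matrix with one
#' row per SMILES (rows of `NA` for unparseable input) and named descriptor
#' columns. The shipped `"rdkit"` backend calls the Python RDKit via
#' `python` on the PATH and computes its full 2D descriptor panel — an
#' open-source stand-in for proprietary descriptor software, not a
#' reproduction of it.
#'
#' @param name backend name.
#' @param fun backend function.
#' @export
register_descriptor_backend <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = descriptor_backends)
  invisible(name)
}

#' Compute descriptors from SMILES strings
#'
#' @param smiles character vector of SMILES; names (or `ids`) become row
#'   names.
#' @param backend backend name previously registered; `"rdkit"` is shipped.
#' @param ids optional compound ids.
#' @return numeric descriptor matrix; unparseable SMILES give all-`NA` rows
#'   and are logged.
#' @export
compute_descriptors <- function(smiles, backend = "rdkit", ids = NULL) {
  if (!exists(backend, envir = descriptor_backends))
    stop("unknown descriptor backend '", backend, "'; register one with ",
         "register_descriptor_backend() or use the shipped 'rdkit' backend")
  fun <- get(backend, envir = descriptor_backends)
  x <- fun(as.character(smiles))
  if (!is.null(ids)) rownames(x) <- ids
  else if (!is.null(names(smiles))) rownames(x) <- names(smiles)
  bad <- rowSums(!is.na(x)) == 0
  if (any(bad))
    message("compute_descriptors: ", sum(bad),
            " SMILES failed to parse: ",
            paste(utils::head(which(bad), 5), collapse = ", "))
  x
}

rdkit_backend <- function(smiles) {
  py <- Sys.which("python")
  if (!nzchar(py))
    stop("descriptor backend 'rdkit' needs `python` with the rdkit package ",
         "on the PATH; install RDKit or supply a precomputed descriptor ",
         "table via read_descriptor_table()")
  script <- system.file("python", "rdkit_panel.py", package = "dilisvm")
  fin <- tempfile(fileext = ".txt"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)))
  writeLines(smiles, fin)
  status <- system2(py, c(script, fin, fout), stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(fout))
    stop("descriptor backend 'rdkit' failed; is the Python rdkit package ",
         "importable? Try `python -c 'import rdkit'`.")
  out <- read.csv(fout, check.names = FALSE)
  as.matrix(out)
}

# registered at load time; the capability check happens on first use
.onLoad <- function(libname, pkgname) {
  register_descriptor_backend("rdkit", rdkit_backend)
}

# ---- preprocessing ---------------------------------------------------------

#' Prefilter, impute and standardize a descriptor matrix
#'
#' Drops degenerate descriptors (all-missing, fewer than two observed
#' values, or zero variance) and exact duplicate columns (first name in
#' column order kept), imputes remaining missing values with the
#' training-set median, and centers/scales every retained descriptor to
#' mean 0, standard deviation 1. Margin-based classifiers are
#' scale-sensitive, so standardization is on by default.
#'
#' The returned `scaling` object stores everything needed to transform new
#' compounds identically at prediction time; applying it to the fitting set
#' reproduces the preprocessed matrix exactly.
#'
#' @param x numeric matrix (compounds x descriptors) with `NA` for missing.
#' @param standardize center/scale after imputation (default TRUE).
#' @return list with `x` (reduced, imputed, scaled matrix) and `scaling`
#'   (class `scaling_params`).
#' @export
preprocess_descriptors <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("descriptor columns must be named")
  n_obs <- colSums(!is.na(x))
  sds <- apply(x, 2, function(col) sd(col, na.rm = TRUE))
  degenerate <- n_obs < 2 | is.na(sds) | sds == 0
  keep <- colnames(x)[!degenerate]
  if (length(keep) == 0)
    stop("all descriptors are degenerate (constant or unobserved)")
  medians <- apply(x[, keep, drop = FALSE], 2,
                   function(col) median(col, na.rm = TRUE))
  imputed <- x[, keep, drop = FALSE]
  for (j in seq_along(keep)) {
    mis <- is.na(imputed[, j])
    if (any(mis)) imputed[mis, j] <- medians[j]
  }
  dup <- duplicated(t(imputed))
  keep2 <- keep[!dup]
  imputed <- imputed[, keep2, drop = FALSE]
  center <- colMeans(imputed)
  scale_ <- apply(imputed, 2, sd)
  if (!standardize) { center[] <- 0; scale_[] <- 1 }
  params <- structure(list(features = keep2,
                           medians = medians[keep2],
                           center = center, scale = scale_,
                           standardize = standardize,
                           dropped_degenerate = colnames(x)[degenerate],
                           dropped_duplicate = keep[dup],
                           fitted_on = rownames(x) %||% character()),
                      class = "scaling_params")
  list(x = apply_scaling(params, x), scaling = params)
}

#' Apply stored scaling parameters to a raw descriptor matrix
#'
#' @param params a `scaling_params` object from [preprocess_descriptors()].
#' @param x raw numeric descriptor matrix containing at least the retained
#'   features (missing cells allowed; imputed with the stored medians).
#' @return matrix restricted to the retained features, imputed and scaled.
#' @export
apply_scaling <- function(params, x) {
  x <- as.matrix(x)
  missing_feats <- setdiff(params$features, colnames(x))
  if (length(missing_feats) > 0)
    stop("matrix lacks required descriptors: ",
         paste(utils::head(missing_feats, 5), collapse = ", "))
  out <- x[, params$features, drop = FALSE]
  for (j in seq_along(params$features)) {
    mis <- is.na(out[, j])
    if (any(mis)) out[mis, j] <- params$medians[j]
  }
  out <- sweep(out, 2, params$center, "-")
  sweep(out, 2, params$scale, "/")
}

#' Serialize scaling parameters to JSON
#' @param params a `scaling_params` object.
#' @param path JSON file path.
#' @export
write_scaling <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaling
#' @export
read_scaling <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("medians", "center", "scale"))
    raw[[f]] <- setNames(as.numeric(raw[[f]]), raw$features)
  structure(raw, class = "scaling_params")
}
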