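# Delimited-text I/O for activity panels, descriptor tables and distance
# matrices, plus compound-library ingestion and admission filtering.
#
# Dialect: comma-separated, UTF-8, first row = column ids, first column =
# row ids. Matrices are plain numeric matrices with dimnames.

read_numeric_csv <- function(path, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(what, " must have an id column and at least one data column", call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate row id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  cols <- names(df)[-1]
  if (anyDuplicated(cols)) {
    stop("duplicate column id(s): ", paste(unique(cols[duplicated(cols)]), collapse = ", "),
         call. = FALSE)
  }
  body <- df[-1]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v)) else v <- as.numeric(v)
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("non-numeric or missing cell at row '%s', column '%s'",
                   ids[bad], cols[j]), call. = FALSE)
    }
    body[[j]] <- v
  }
  m <- as.matrix(body)
  dimnames(m) <- list(ids, cols)
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at row '%s', column '%s'",
                 ids[bad[1]], cols[bad[2]]), call. = FALSE)
  }
  m
}

write_numeric_csv <- function(x, path) {
  # full 17-significant-digit precision so tables round-trip bit-exactly
  body <- apply(x, 2, function(v) sprintf("%.17g", v))
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(x))
  lines <- c(paste(c("id", colnames(x)), collapse = ","),
             paste(rownames(x), apply(body, 1, paste, collapse = ","), sep = ","))
  if (nrow(x) == 0) lines <- lines[1]
  writeLines(lines, path)
  invisible(path)
}

#' Read an odor-by-receptor activity table
#'
#' Reads a complete response panel (spikes/s; negative values denote
#' below-baseline firing) from CSV. Cells must all be present and numeric;
#' a missing or non-numeric cell is an error naming the offending row and
#' column, since the training design is a complete panel and imputation is
#' deliberately not offered.
#'
#' @param path CSV file; first column odor ids, remaining columns receptors.
#' @param orientation `"odors_by_receptors"` (default) if rows are odors,
#'   `"receptors_by_odors"` if the file is transposed.
#' @return Numeric matrix, odors in rows, receptors in columns, file order
#'   preserved.
#' @export
read_activity_table <- function(path, orientation = c("odors_by_receptors", "receptors_by_odors")) {
  orientation <- match.arg(orientation)
  m <- read_numeric_csv(path, "activity table")
  if (orientation == "receptors_by_odors") m <- t(m)
  m
}

#' Write an activity table to CSV
#'
#' @param activity matrix as returned by [read_activity_table()].
#' @param path output file.
#' @export
write_activity_table <- function(activity, path) {
  write_numeric_csv(activity, path)
}

#' Read a compound-by-descriptor table
#'
#' @param path CSV file; first column compound ids, remaining columns
#'   molecular descriptor ids.
#' @return Numeric matrix, compounds in rows and descriptors in columns.
#'   Non-finite values (descriptor software failures) are rejected.
#' @export
read_descriptor_table <- function(path) {
  read_numeric_csv(path, "descriptor table")
}

#' Write a descriptor table to CSV
#'
#' @param descriptors compound-by-descriptor matrix.
#' @param path output file.
#' @export
write_descriptor_table <- function(descriptors, path) {
  write_numeric_csv(descriptors, path)
}

#' Read a compound-by-compound distance matrix
#'
#' Supports externally computed distances (e.g. atom-pair or
#' maximum-common-substructure comparisons done elsewhere). The matrix is
#' validated: square with matching ids, symmetric to 1e-9, nonnegative,
#' zero diagonal.
#'
#' @param path CSV file with identical row and column ids.
#' @return Symmetric numeric matrix with `provenance` attribute `"external"`.
#' @export
read_distance_matrix <- function(path) {
  m <- read_numeric_csv(path, "distance matrix")
  validate_distances(m, tol = 1e-9)
  attr(m, "provenance") <- "external"
  m
}

#' Write a distance matrix to CSV
#'
#' @param distances symmetric matrix.
#' @param path output file.
#' @export
write_distance_matrix <- function(distances, path) {
  write_numeric_csv(distances, path)
}

validate_distances <- function(m, tol = 1e-9) {
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("distance matrix must be square with matching row/column ids", call. = FALSE)
  }
  asym <- max(abs(m - t(m)))
  if (asym > tol) stop(sprintf("asymmetric distance matrix (max |d_ij - d_ji| = %g)", asym), call. = FALSE)
  if (any(m < 0)) stop("negative distance entries", call. = FALSE)
  if (any(abs(diag(m)) > tol)) stop("nonzero diagonal in distance matrix", call. = FALSE)
  invisible(m)
}

#' Assemble a compound library
#'
#' A library is a data frame with one row per compound: `id`, optional
#' `structure` (SMILES), optional `mol_weight` (unified atomic mass units)
#' and `atom_set` (list column of element symbols, implicit hydrogens
#' included). Properties missing for compounds with a structure are derived
#' with ChemmineR/OpenBabel.
#'
#' @param id character vector of unique compound ids.
#' @param structure optional SMILES strings (NA where unknown).
#' @param mol_weight optional molecular weights.
#' @param atom_set optional list of character vectors of element symbols.
#' @param source_tag optional free-text origin label.
#' @return data.frame of class `compound_library`.
#' @export
compound_library <- function(id, structure = NULL, mol_weight = NULL,
                             atom_set = NULL, source_tag = NULL) {
  id <- as.character(id)
  if (length(id) == 0) {
    lib <- data.frame(id = character(), structure = character(),
                      mol_weight = numeric(), stringsAsFactors = FALSE)
    lib$atom_set <- list()
    lib$source_tag <- character()
    class(lib) <- c("compound_library", "data.frame")
    return(lib)
  }
  if (any(!nzchar(id))) stop("empty compound id", call. = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate compound id(s): ", paste(unique(id[duplicated(id)]), collapse = ", "),
         call. = FALSE)
  }
  n <- length(id)
  lib <- data.frame(id = id, stringsAsFactors = FALSE)
  lib$structure <- if (is.null(structure)) rep(NA_character_, n) else as.character(structure)
  lib$mol_weight <- if (is.null(mol_weight)) rep(NA_real_, n) else as.numeric(mol_weight)
  lib$atom_set <- if (is.null(atom_set)) rep(list(NULL), n) else atom_set
  lib$source_tag <- if (is.null(source_tag)) rep(NA_character_, n) else as.character(source_tag)
  class(lib) <- c("compound_library", "data.frame")
  lib
}

#' Read a SMILES file as a compound library
#'
#' One compound per line: a SMILES string, optionally followed by a tab and
#' an id. Compounds without an explicit id are named `cmpd<line>`.
#'
#' @param path SMILES file.
#' @return `compound_library` data frame (properties not yet derived).
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  smi <- vapply(parts, `[[`, "", 1)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2 && nzchar(parts[[i]][2])) parts[[i]][2]
    else sprintf("cmpd%d", i)
  }, "")
  compound_library(id = ids, structure = smi)
}

# Derive mol_weight and atom_set from SMILES structures via
# ChemmineR/OpenBabel for rows lacking them.
derive_compound_properties <- function(lib) {
  need <- which(is.na(lib$mol_weight) |
                  vapply(lib$atom_set, is.null, logical(1)))
  if (length(need) == 0) return(lib)
  has_struct <- !is.na(lib$structure[need]) & nzchar(lib$structure[need])
  if (any(!has_struct)) {
    stop("compound(s) lacking both structure and precomputed properties: ",
         paste(lib$id[need[!has_struct]], collapse = ", "), call. = FALSE)
  }
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("ChemmineR is required to derive properties from structures", call. = FALSE)
  }
  smi <- lib$structure[need]
  names(smi) <- lib$id[need]
  sdf <- ChemmineR::smiles2sdf(smi)
  props <- ChemmineR::propOB(sdf)
  counts <- ChemmineR::atomcountMA(sdf, addH = TRUE)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1, dimnames = list(lib$id[need][1], names(counts)))
  for (k in seq_along(need)) {
    i <- need[k]
    if (is.na(lib$mol_weight[i])) lib$mol_weight[i] <- props$MW[k]
    if (is.null(lib$atom_set[[i]])) {
      lib$atom_set[[i]] <- colnames(counts)[counts[k, ] > 0]
    }
  }
  lib
}

#' Filter a compound library for screening admission
#'
#' Retains compounds with molecular weight strictly below `max_mw` and an
#' element composition contained in `allowed_atoms`. Defaults are the
#' admission criteria for a volatile odorant library: MW < 200 u and atoms
#' drawn from C, O, N, H, I, Cl, S, F. Comparison is by element symbol set
#' (counts and isotopes ignored); implicit hydrogens count.
#'
#' @param lib `compound_library` data frame.
#' @param max_mw molecular-weight threshold in u (strict `<`).
#' @param allowed_atoms character vector of admissible element symbols.
#' @return the retained rows of `lib`, order preserved, with derived
#'   `mol_weight`/`atom_set` filled in.
#' @export
filter_library <- function(lib, max_mw = 200,
                           allowed_atoms = c("C", "O", "N", "H", "I", "Cl", "S", "F")) {
  stopifnot(is.data.frame(lib))
  if (nrow(lib) == 0) return(lib)
  lib <- derive_compound_properties(lib)
  keep <- lib$mol_weight < max_mw &
    vapply(lib$atom_set, function(a) all(a %in% allowed_atoms), logical(1))
  lib[keep, , drop = FALSE]
}

#' @export
print.compound_library <- function(x, ...) {
  cat(sprintf("compound library: %d compounds\n", nrow(x)))
  if (nrow(x) > 0) {
    print.data.frame(utils::head(x, 10))
    if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  }
  invisible(x)
}
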