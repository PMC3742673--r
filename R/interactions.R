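# Residue-pair interaction matrices and peptide sequences.

#' The 20 standard one-letter amino-acid codes
#'
#' Residue ordering used throughout the package (and by the packaged
#' interaction table): hydrophobic residues first, then charged, then polar.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "G", "V", "L", "I", "P", "F", "M", "W", "C",
                 "D", "E", "R", "K", "H", "N", "Q", "S", "T", "Y")

# Unordered like-charge pairs whose contact energy is repulsive (positive)
# under the sign convention of the packaged simulated matrix.
LIKE_CHARGE_PAIRS <- list(c("D", "D"), c("D", "E"), c("E", "E"),
                          c("R", "R"), c("R", "K"), c("K", "K"))

#' Default 12-residue peptide sequence
#'
#' The dodecapeptide HSSYWYAFNNKT used as the package's worked example of
#' sequence-specific self-assembly.
#'
#' @format Character scalar.
#' @export
P1_SEQUENCE <- "HSSYWYAFNNKT"

new_interaction_matrix <- function(values, provenance) {
  stopifnot(is.matrix(values), nrow(values) == 20L, ncol(values) == 20L)
  structure(values, class = "interaction_matrix", provenance = provenance)
}

validate_interaction_matrix <- function(m, context = "interaction matrix") {
  if (!identical(rownames(m), AA_ALPHABET) || !identical(colnames(m), AA_ALPHABET))
    stop(context, ": rows/columns must be labeled with the 20 one-letter codes ",
         "in a consistent order", call. = FALSE)
  if (anyNA(m)) {
    bad <- which(is.na(m) & is.na(t(m)), arr.ind = TRUE)[1, ]
    stop(context, ": missing value for pair (",
         AA_ALPHABET[bad[1]], ",", AA_ALPHABET[bad[2]], ")", call. = FALSE)
  }
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
    stop(context, ": contradictory (a,b) vs (b,a) entries; matrix must be ",
         "symmetric", call. = FALSE)
  invisible(m)
}

# Symmetric completion of a matrix read with NAs in one triangle.  Errors if
# both triangles are present but disagree.
complete_symmetric <- function(m) {
  both <- !is.na(m) & !is.na(t(m))
  if (any(m[both] != t(m)[both])) {
    bad <- which(both & (m != t(m)), arr.ind = TRUE)[1, ]
    stop("contradictory values for pair (", rownames(m)[bad[1]], ",",
         colnames(m)[bad[2]], ")", call. = FALSE)
  }
  fill <- is.na(m) & !is.na(t(m))
  m[fill] <- t(m)[fill]
  m
}

#' Load the packaged simulated residue-pair interaction matrix
#'
#' Reads the packaged table of minimum pairwise interaction-energy magnitudes
#' between the 20 amino acids (kcal/mol, derived from all-atom simulations of
#' isolated capped residue pairs in vacuum) and applies the sign convention:
#' the six like-charge pairs D-D, D-E, E-E, R-R, R-K and K-K are repulsive
#' (positive), every other pair is attractive (negative).  Within the
#' coarse-grained model these values are used directly as dimensionless well
#' depths, with temperature expressed in the same reduced units.
#'
#' The packaged table stores magnitudes exactly as published so the data file
#' can be checked verbatim against its source; signing happens here.  Two
#' entries (H-V and H-L) carry an explicit minus sign in the published table
#' even though the stated convention already makes them negative; by default
#' they are treated as attractive with magnitude 9 and a message notes the
#' anomaly.
#'
#' @param h_anomaly How to sign the H-V and H-L entries: `"attractive"`
#'   (default, magnitude 9 with negative sign) or `"repulsive"` (+9, reading
#'   the printed minus sign as a deliberate exception that flips under the
#'   global sign rule).
#' @param quiet Suppress the anomaly message.
#' @return An `interaction_matrix`: a symmetric signed 20x20 numeric matrix
#'   with residue dimnames and a `provenance` attribute set to `"simulated"`.
#' @examples
#' m <- load_simulated_matrix(quiet = TRUE)
#' epsilon(m, "A", "A")   # -6, attractive
#' epsilon(m, "D", "E")   # +68, like-charge repulsion
#' @export
load_simulated_matrix <- function(h_anomaly = c("attractive", "repulsive"),
                                  quiet = FALSE) {
  h_anomaly <- match.arg(h_anomaly)
  path <- system.file("extdata", "simulated_pair_energies.csv",
                      package = "pepbfm", mustWork = TRUE)
  raw <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  storage.mode(raw) <- "double"
  raw <- raw[AA_ALPHABET, AA_ALPHABET]
  raw <- complete_symmetric(raw)

  neg_printed <- which(raw < 0 & lower.tri(raw, diag = TRUE), arr.ind = TRUE)
  if (nrow(neg_printed) > 0 && !quiet) {
    pairs <- apply(neg_printed, 1, function(ij)
      paste0(rownames(raw)[ij[1]], "-", colnames(raw)[ij[2]]))
    message("pair(s) ", paste(pairs, collapse = ", "),
            " carry an explicit minus sign in the source table; treating as ",
            h_anomaly, " with magnitude ", paste(abs(raw[neg_printed]), collapse = ", "))
  }

  signed <- -abs(raw)
  for (p in LIKE_CHARGE_PAIRS) {
    signed[p[1], p[2]] <- abs(raw[p[1], p[2]])
    signed[p[2], p[1]] <- abs(raw[p[2], p[1]])
  }
  if (h_anomaly == "repulsive") {
    signed["H", "V"] <- signed["V", "H"] <- abs(raw["H", "V"])
    signed["H", "L"] <- signed["L", "H"] <- abs(raw["H", "L"])
  }
  m <- new_interaction_matrix(signed, provenance = "simulated")
  validate_interaction_matrix(m, "simulated matrix")
  m
}

#' Load a residue-pair interaction matrix from CSV
#'
#' Accepts a CSV with a header row and first column of one-letter residue
#' codes (any order); either triangle, or both, may be filled.  Values are
#' taken as given: no sign convention is applied, so knowledge-based contact
#' matrices (e.g. a Miyazawa-Jernigan table) can be supplied directly.
#'
#' @param path CSV file path.
#' @param provenance Free-form tag recorded on the matrix, e.g.
#'   `"knowledge_based"` or `"custom"`.
#' @return An `interaction_matrix`.
#' @seealso [write_matrix()] for the inverse operation.
#' @export
load_matrix_file <- function(path, provenance = "custom") {
  raw <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  storage.mode(raw) <- "double"
  labs_r <- rownames(raw)
  labs_c <- colnames(raw)
  unknown <- setdiff(union(labs_r, labs_c), AA_ALPHABET)
  if (length(unknown) > 0)
    stop("unknown residue label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(AA_ALPHABET, intersect(labs_r, labs_c))
  if (length(missing) > 0)
    stop("matrix file is missing residue(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  raw <- raw[AA_ALPHABET, AA_ALPHABET]
  raw <- complete_symmetric(raw)
  m <- new_interaction_matrix(raw, provenance = provenance)
  validate_interaction_matrix(m, basename(path))
  m
}

#' Synthetic knowledge-based-style contact matrix
#'
#' A packaged stand-in for published knowledge-based residue contact-energy
#' tables (such as the Miyazawa-Jernigan matrix).  It is *synthetic*: built
#' from the Kyte-Doolittle hydropathy scale as
#' \eqn{e_{ij} = -0.39 (h_i + h_j) + 0.8 q_i q_j} (shifted hydropathies
#' \eqn{h}, formal side-chain charges \eqn{q}), which reproduces the broad
#' structure of such tables — strong hydrophobic-hydrophobic attraction
#' (down to about -7), weak polar pairs, repulsive like-charge pairs — at
#' their typical magnitude, roughly 4x smaller than the packaged simulated
#' matrix.  Use it to exercise the knowledge-based workflow; for real
#' comparisons supply the published table via [load_matrix_file()].
#'
#' @return An `interaction_matrix` with provenance `"knowledge_based_synthetic"`.
#' @export
kb_synthetic_matrix <- function() {
  path <- system.file("extdata", "kb_synthetic.csv", package = "pepbfm",
                      mustWork = TRUE)
  load_matrix_file(path, provenance = "knowledge_based_synthetic")
}

#' Write an interaction matrix to CSV
#'
#' Writes the full symmetric 20x20 matrix with residue row/column labels.
#' `load_matrix_file()` on the result reproduces all 210 pair values exactly.
#'
#' @param m An `interaction_matrix` (or plain labeled 20x20 matrix).
#' @param path Output CSV path.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(as.matrix(unclass(m)), check.names = FALSE)
  utils::write.csv(df, path, quote = FALSE, row.names = TRUE)
  invisible(path)
}

#' Pair interaction energy lookup
#'
#' Symmetric lookup of the signed pair energy \eqn{\epsilon_{ab}}; negative
#' values are attractive, positive repulsive.
#'
#' @param m An `interaction_matrix`.
#' @param a,b One-letter residue codes.
#' @return Signed numeric energy.
#' @export
epsilon <- function(m, a, b) {
  if (!all(c(a, b) %in% AA_ALPHABET))
    stop("invalid residue code: ", paste(setdiff(c(a, b), AA_ALPHABET),
                                         collapse = ", "), call. = FALSE)
  unclass(m)[a, b]
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("Residue-pair interaction matrix (provenance: ",
      attr(x, "provenance"), ")\n", sep = "")
  cat("  ", sum(x[upper.tri(x, diag = TRUE)] > 0), " repulsive / ",
      sum(x[upper.tri(x, diag = TRUE)] < 0), " attractive unordered pairs; ",
      "range [", min(x), ", ", max(x), "]\n", sep = "")
  invisible(x)
}

#' Parse a peptide sequence
#'
#' Accepts a plain one-letter string (`"HSSYWYAFNNKT"`), inline FASTA text
#' (a string starting with `">"`), or a path to a FASTA file (read with
#' Biostrings when available, otherwise with a minimal reader).  Residue
#' positions are 1-based.
#'
#' @param x Sequence string, FASTA text, or FASTA file path.
#' @param name Optional name; defaults to the FASTA header or `"peptide"`.
#' @return A `peptide` object: character vector of residues with a `name`
#'   attribute.
#' @examples
#' p <- parse_sequence("HSSYWYAFNNKT")
#' length(p)   # 12
#' p[11]       # "K"
#' @export
parse_sequence <- function(x, name = NULL) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  if (!startsWith(x, ">") && file.exists(x) && !grepl("^[A-Za-z]+$", x)) {
    x <- paste(readLines(x), collapse = "\n")
  }
  if (startsWith(x, ">")) {
    lines <- strsplit(x, "\n", fixed = TRUE)[[1]]
    if (is.null(name))
      name <- sub("^>\\s*(\\S+).*$", "\\1", lines[1])
    body <- lines[-1]
    body <- body[!startsWith(body, ">")]   # first record only
    x <- paste(gsub("\\s", "", body), collapse = "")
  }
  if (is.null(name)) name <- "peptide"
  res <- strsplit(toupper(x), "")[[1]]
  bad <- which(!(res %in% AA_ALPHABET))
  if (length(bad) > 0)
    stop("invalid residue '", res[bad[1]], "' at position ", bad[1],
         call. = FALSE)
  if (length(res) < 2)
    stop("peptide must have at least 2 residues", call. = FALSE)
  structure(res, class = "peptide", name = name)
}

#' @export
print.peptide <- function(x, ...) {
  cat(">", attr(x, "name"), " (", length(x), " residues)\n",
      paste(unclass(x), collapse = ""), "\n", sep = "")
  invisible(x)
}

# Integer residue indices (1..20) into AA_ALPHABET for a peptide.
sequence_indices <- function(p) {
  match(unclass(p), AA_ALPHABET)
}
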