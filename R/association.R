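#' Construct a drug-by-side-effect association matrix
#'
#' Validates and returns the binary incidence matrix X at the core of the
#' model: `X[i, j] = 1` when drug i is known to induce side effect j, 0
#' otherwise. Rows are drugs, columns are side effects; both dimensions carry
#' unique identifiers as dimnames. The matrix is returned as a plain base
#' matrix so ordinary matrix algebra applies.
#'
#' @param values numeric matrix of 0/1 flags, or anything coercible to one.
#' @param drug_ids,side_effect_ids optional character vectors of identifiers;
#'   default to existing dimnames, else `drug1..n` / `se1..m`.
#' @return the validated numeric matrix with identifier dimnames.
#' @export
association_matrix <- function(values, drug_ids = rownames(values),
                               side_effect_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(drug_ids)) drug_ids <- paste0("drug", seq_len(nrow(values)))
  if (is.null(side_effect_ids)) {
    side_effect_ids <- paste0("se", seq_len(ncol(values)))
  }
  drug_ids <- as.character(drug_ids)
  side_effect_ids <- as.character(side_effect_ids)
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("association matrix must have at least one drug and one side effect")
  }
  if (anyDuplicated(drug_ids)) stop("duplicate drug identifiers")
  if (anyDuplicated(side_effect_ids)) stop("duplicate side effect identifiers")
  if (length(drug_ids) != nrow(values) ||
      length(side_effect_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  storage.mode(values) <- "double"
  if (anyNA(values) || !all(values == 0 | values == 1)) {
    stop("association matrix entries must be exactly 0 or 1")
  }
  dimnames(values) <- list(drug_ids, side_effect_ids)
  values
}

#' Build an association matrix from long-format pairs
#'
#' @param drug,side_effect character vectors of equal length, one known
#'   association per element.
#' @param drug_ids,side_effect_ids optional identifier universes; defaults to
#'   the sorted unique values observed.
#' @return an [association_matrix()].
#' @export
association_from_pairs <- function(drug, side_effect,
                                   drug_ids = NULL, side_effect_ids = NULL) {
  drug <- as.character(drug)
  side_effect <- as.character(side_effect)
  stopifnot(length(drug) == length(side_effect))
  if (is.null(drug_ids)) drug_ids <- sort(unique(drug))
  if (is.null(side_effect_ids)) side_effect_ids <- sort(unique(side_effect))
  if (!all(drug %in% drug_ids)) stop("drug identifier outside universe")
  if (!all(side_effect %in% side_effect_ids)) {
    stop("side effect identifier outside universe")
  }
  x <- matrix(0, length(drug_ids), length(side_effect_ids),
              dimnames = list(drug_ids, side_effect_ids))
  x[cbind(match(drug, drug_ids), match(side_effect, side_effect_ids))] <- 1
  association_matrix(x)
}
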