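#' Validate a pedigree table
#'
#' A pedigree is a data frame with columns `id`, `father`, `mother`, `sex`
#' and (optionally) `family`.  Missing parents are coded `"0"` (the usual
#' PLINK-style convention).  Individuals must have unique ids, named parents
#' must themselves be pedigree members of the appropriate sex, both parents
#' are either known or unknown together for simulated pedigrees (half-known
#' parentage is allowed for supplied pedigrees), and no individual may be
#' its own ancestor.
#'
#' @param ped data frame with columns `id`, `father`, `mother`, `sex`.
#' @return `ped`, invisibly, with ids coerced to character; an error is
#'   thrown if the pedigree is structurally invalid.
#' @export
validate_pedigree <- function(ped) {
  need <- c("id", "father", "mother", "sex")
  if (!all(need %in% names(ped)))
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  ped$id <- as.character(ped$id)
  ped$father <- as.character(ped$father)
  ped$mother <- as.character(ped$mother)
  if (anyDuplicated(ped$id)) stop("pedigree ids are not unique")
  if (!all(ped$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  known_f <- ped$father != "0"
  known_m <- ped$mother != "0"
  if (!all(ped$father[known_f] %in% ped$id))
    stop("father(s) not in pedigree: ",
         paste(setdiff(ped$father[known_f], ped$id), collapse = ", "))
  if (!all(ped$mother[known_m] %in% ped$id))
    stop("mother(s) not in pedigree: ",
         paste(setdiff(ped$mother[known_m], ped$id), collapse = ", "))
  sex <- stats::setNames(ped$sex, ped$id)
  if (!all(sex[ped$father[known_f]] == "M")) stop("some fathers are not male")
  if (!all(sex[ped$mother[known_m]] == "F")) stop("some mothers are not female")
  pedigree_order(ped)  # errors on cycles
  invisible(ped)
}

# Topological order (parents before children); errors on cyclic pedigrees.
pedigree_order <- function(ped) {
  id <- as.character(ped$id)
  fa <- match(as.character(ped$father), id)  # NA = founder link
  mo <- match(as.character(ped$mother), id)
  n <- length(id)
  placed <- logical(n)
  ord <- integer(n)
  k <- 0L
  repeat {
    # a row is ready when each known parent is already placed
    ready <- !placed &
      (is.na(fa) | placed[ifelse(is.na(fa), 1L, fa)]) &
      (is.na(mo) | placed[ifelse(is.na(mo), 1L, mo)])
    if (!any(ready)) break
    idx <- which(ready)
    ord[k + seq_along(idx)] <- idx
    k <- k + length(idx)
    placed[idx] <- TRUE
  }
  if (k < n)
    stop("pedigree contains a cycle (an individual is its own ancestor): ",
         paste(id[!placed], collapse = ", "))
  ord
}

#' Additive (numerator) relationship matrix from a pedigree
#'
#' Builds the additive genetic relationship matrix A (twice the kinship
#' coefficients) by the tabular method: processing individuals with parents
#' before children,
#' \deqn{A_{ij} = \tfrac12 (A_{j,f(i)} + A_{j,m(i)}), \qquad
#'       A_{ii} = 1 + \tfrac12 A_{f(i),m(i)},}
#' with missing-parent terms contributing zero.  The result is symmetric
#' positive semidefinite; the diagonal exceeds 1 for inbred individuals.
#' This matrix is the covariance structure of the polygenic random effect
#' used to account for relatedness of family members in the mixed models.
#'
#' @param ped pedigree data frame (see [validate_pedigree()]).
#' @return an n x n symmetric matrix with dimnames equal to `ped$id`.
#' @examples
#' trio <- data.frame(id = c("f", "m", "c"), father = c("0", "0", "f"),
#'                    mother = c("0", "0", "m"), sex = c("M", "F", "M"))
#' kinship_matrix(trio)["f", "c"]  # parent-offspring: 0.5
#' @export
kinship_matrix <- function(ped) {
  ped <- validate_pedigree(ped)
  id <- ped$id
  n <- length(id)
  ord <- pedigree_order(ped)
  fa <- match(ped$father, id)
  mo <- match(ped$mother, id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  done <- integer(0)
  for (i in ord) {
    f <- fa[i]; m <- mo[i]
    if (length(done)) {
      row <- 0.5 * ((if (!is.na(f)) A[done, f] else 0) +
                    (if (!is.na(m)) A[done, m] else 0))
      A[done, i] <- row
      A[i, done] <- row
    }
    A[i, i] <- 1 + 0.5 * (if (!is.na(f) && !is.na(m)) A[f, m] else 0)
    done <- c(done, i)
  }
  A
}

#' Exchangeable family relationship matrix
#'
#' Fallback relatedness structure when only family identifiers (no pedigree
#' links) are available: a block-diagonal matrix of ones within each family,
#' i.e. all members of a family are exchangeable and families are unrelated.
#' Using this matrix in [fit_polygenic_lmm()] is equivalent to a mixed model
#' with a random intercept per family.
#'
#' @param family vector of family identifiers, one per individual.
#' @param ids optional individual ids used as dimnames.
#' @return an n x n symmetric 0/1 matrix.
#' @export
family_matrix <- function(family, ids = NULL) {
  family <- as.character(family)
  A <- outer(family, family, `==`) * 1
  if (!is.null(ids)) dimnames(A) <- list(ids, ids)
  A
}

#' Read and write PLINK-style pedigree files
#'
#' Four whitespace-separated columns: id, father, mother, sex (`M`/`F`),
#' with `0` for a missing parent.  An optional fifth column holds the
#' family identifier.
#'
#' @param ped pedigree data frame.
#' @param path file path.
#' @return `read_pedigree()` returns the pedigree data frame.
#' @export
write_pedigree <- function(ped, path) {
  cols <- intersect(c("id", "father", "mother", "sex", "family"), names(ped))
  utils::write.table(ped[cols], path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  validate_pedigree(ped)
  ped
}
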