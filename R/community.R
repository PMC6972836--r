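#' Site-by-species community matrix
#'
#' Construct and validate a community matrix: an `n` sites by `p` species
#' table of responses.  Three response families are supported:
#' `"binary"` presence/absence (entries 0/1), `"count"` abundances
#' (non-negative integers) and `"ordinal"` cover classes (entries in
#' `1, ..., K`, e.g. Braun-Blanquet or Daubenmire classes recoded to
#' consecutive integers starting at 1).
#'
#' @param x numeric matrix (or object coercible to one) with sites as rows
#'   and species as columns.  Missing values are not allowed.
#' @param family one of `"binary"`, `"count"`, `"ordinal"`.
#' @param K integer number of ordinal classes (`family = "ordinal"` only);
#'   defaults to the maximum observed class.
#' @param site_labels,species_labels optional character labels; default to
#'   the dimnames of `x` or `site1, ...` / `sp1, ...`.
#'
#' @return An object of class `"community_matrix"`: the numeric matrix with
#'   attributes `family` and (for ordinal data) `K`.
#' @examples
#' y <- community_matrix(matrix(c(0, 1, 1, 0), 2, 2), family = "binary")
#' family(y)
#' @export
community_matrix <- function(x, family = c("binary", "count", "ordinal"),
                             K = NULL, site_labels = NULL,
                             species_labels = NULL) {
  family <- match.arg(family)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("a community matrix needs at least 2 sites and 2 species")
  if (anyNA(x))
    stop("missing entries are not allowed in a community matrix")
  if (is.null(site_labels))
    site_labels <- rownames(x) %||% paste0("site", seq_len(nrow(x)))
  if (is.null(species_labels))
    species_labels <- colnames(x) %||% paste0("sp", seq_len(ncol(x)))
  dimnames(x) <- list(site_labels, species_labels)

  bad <- switch(family,
    binary  = which(!(x %in% c(0, 1))),
    count   = which(x < 0 | x != floor(x)),
    ordinal = {
      if (is.null(K)) K <- max(x)
      K <- as.integer(K)
      if (K < 2L) stop("ordinal data need K >= 2 classes")
      which(x < 1 | x > K | x != floor(x))
    })
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(x))
    stop(sprintf(
      "invalid %s value %g at site '%s', species '%s' (row %d, column %d)",
      family, x[bad[1L]], site_labels[ij[1L]], species_labels[ij[2L]],
      ij[1L], ij[2L]))
  }
  structure(x, family = family, K = if (family == "ordinal") K,
            class = c("community_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
family.community_matrix <- function(object, ...) attr(object, "family")

#' @export
print.community_matrix <- function(x, ...) {
  fam <- attr(x, "family")
  cat(sprintf("Community matrix: %d sites x %d species, family '%s'%s\n",
              nrow(x), ncol(x), fam,
              if (fam == "ordinal") sprintf(" (K = %d classes)",
                                            attr(x, "K")) else ""))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Read a community matrix from a delimited text file
#'
#' The expected layout is a header row of species names and a first column
#' of site labels, i.e. the natural `write.csv` layout of a site-by-species
#' table.  The delimiter is auto-detected among comma and tab unless given.
#'
#' @param path file path.
#' @param family,K response family and ordinal class count, as in
#'   [community_matrix()].
#' @param sep field delimiter; `NULL` (default) auto-detects comma vs tab.
#' @param transpose set `TRUE` if the file stores species as rows.
#' @return a [community_matrix()].
#' @export
read_community <- function(path, family = c("binary", "count", "ordinal"),
                           K = NULL, sep = NULL, transpose = FALSE) {
  family <- match.arg(family)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    l1 <- readLines(path, n = 1L)
    sep <- if (grepl("\t", l1)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(as.numeric(m))) & !is.na(m))[1L]
    ij <- arrayInd(bad, dim(m))
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                 m[bad], rownames(m)[ij[1L]], colnames(m)[ij[2L]]))
  }
  if (transpose) m <- t(m)
  community_matrix(m, family = family, K = K)
}

#' Write a community matrix to a delimited text file
#'
#' @param y a [community_matrix()].
#' @param path output file path.
#' @param sep field delimiter (default comma).
#' @export
write_community <- function(y, path, sep = ",") {
  stopifnot(inherits(y, "community_matrix"))
  utils::write.table(unclass(y), path, sep = sep, quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Degrade counts to presence/absence
#'
#' Maps an abundance (count) community matrix to a binary one: any positive
#' count becomes a presence.  Used to compare the information content of
#' abundance versus presence records for the same survey.
#'
#' @param y a count-family [community_matrix()].
#' @return a binary [community_matrix()] with the same labels.
#' @examples
#' y <- community_matrix(matrix(c(0, 3, 1, 0), 2, 2), family = "count")
#' degrade_to_presence(y)
#' @export
degrade_to_presence <- function(y) {
  stopifnot(inherits(y, "community_matrix"))
  if (attr(y, "family") != "count")
    stop("degrade_to_presence expects a count-family community matrix")
  community_matrix((unclass(y) > 0) + 0, family = "binary",
                   site_labels = rownames(y), species_labels = colnames(y))
}
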