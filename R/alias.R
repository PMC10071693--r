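#' Gene alias canonicalisation
#'
#' Immune genes are routinely referred to by protein names (GITR, CD141,
#' B7-H3, DC-LAMP, ...) rather than HGNC symbols. An alias map is a named
#' character vector, \code{c(alias = canonical)}; symbols absent from the
#' map are returned unchanged, so canonicalisation is idempotent provided
#' every canonical symbol maps to itself (enforced by
#' \code{validateAliasMap}).
#'
#' @param map Named character vector mapping alias to canonical symbol.
#' @param symbols Character vector of gene symbols.
#' @return \code{canonicalizeSymbols}: character vector of the same length
#'   with aliases replaced; \code{defaultAliasMap}: the alias table shipped
#'   with the package; \code{validateAliasMap}: the map, invisibly, or an
#'   error.
#' @examples
#' canonicalizeSymbols(c("GITR", "CXCL9", "B7-H3"))
#' @name aliases
NULL

#' @rdname aliases
#' @export
defaultAliasMap <- function() {
  path <- system.file("extdata", "gene_aliases.tsv", package = "ipass")
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  map <- stats::setNames(tab$canonical, tab$alias)
  validateAliasMap(map)
  map
}

#' @rdname aliases
#' @export
validateAliasMap <- function(map) {
  if (length(map) == 0L) return(invisible(map))
  if (is.null(names(map)) || any(names(map) == ""))
    stop("alias map must be a named character vector")
  if (anyDuplicated(names(map)))
    stop("alias map has duplicated alias entries: ",
         paste(unique(names(map)[duplicated(names(map))]), collapse = ", "))
  # idempotency: any canonical symbol that appears as an alias must map to
  # itself, otherwise a second pass would keep rewriting
  hit <- unname(map) %in% names(map)
  bad <- unname(map)[hit][map[unname(map)[hit]] != unname(map)[hit]]
  if (length(bad))
    stop("alias map is not idempotent; canonical symbols remapped: ",
         paste(unique(bad), collapse = ", "))
  invisible(map)
}

#' @rdname aliases
#' @export
canonicalizeSymbols <- function(symbols, map = defaultAliasMap()) {
  validateAliasMap(map)
  out <- as.character(symbols)
  hit <- out %in% names(map)
  out[hit] <- unname(map[out[hit]])
  out
}
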