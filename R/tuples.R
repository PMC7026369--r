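#' Relation labels and tuple machinery
#'
#' A retrieved associative path of at most two edges is summarised by its
#' label 2-tuple: the label of the first edge and the label of the second
#' (or `"NULL"` when the path is a single, direct association). Path
#' evaluation classifies that tuple into a relation class by indexing into
#' a fixed table of production rules.
#'
#' @name label-tuples
NULL

#' Valid edge labels.
#' @keywords internal
.relation_labels <- c("SUBSET", "SUPERSET", "COORD")

#' Relation classes a tuple can map to.
#' @keywords internal
.relation_classes <- c("SET_SUPERSET", "SUPERSET_SET", "COORDINATE", "AMBIGUOUS")

#' The production-rule table mapping label 2-tuples to relation classes
#'
#' One row per possible tuple (3 first labels x {SUBSET, SUPERSET, COORD,
#' NULL} second labels = 12 rows), read from the point of view of a path
#' whose origin is the subject term. Direct SUBSET chains, and COORD
#' followed by SUBSET, establish a set-superset (true) relation; the
#' mirrored rows establish superset-set; COORD chains establish a
#' coordinate relation; a SUBSET followed by a SUPERSET (the
#' robin-animal-bird case) and its relatives are ambiguous and carry no
#' decision value.
#'
#' @return A data frame with columns `first`, `second`, `class`.
#' @examples
#' production_table()
#' @export
production_table <- function() {
  data.frame(
    first = c("SUBSET", "SUBSET", "COORD",
              "SUPERSET", "SUPERSET", "SUPERSET",
              "COORD", "COORD",
              "SUBSET", "SUPERSET", "SUBSET", "COORD"),
    second = c("NULL", "SUBSET", "SUBSET",
               "NULL", "SUPERSET", "COORD",
               "NULL", "COORD",
               "SUPERSET", "SUBSET", "COORD", "SUPERSET"),
    class = c("SET_SUPERSET", "SET_SUPERSET", "SET_SUPERSET",
              "SUPERSET_SET", "SUPERSET_SET", "SUPERSET_SET",
              "COORDINATE", "COORDINATE",
              "AMBIGUOUS", "AMBIGUOUS", "AMBIGUOUS", "AMBIGUOUS"),
    stringsAsFactors = FALSE
  )
}

#' Enumerate all valid label 2-tuples
#'
#' @return Data frame with columns `first` and `second` (12 rows; `second`
#'   is the token `"NULL"` for single-edge paths).
#' @export
all_label_tuples <- function() {
  expand.grid(first = .relation_labels,
              second = c(.relation_labels, "NULL"),
              stringsAsFactors = FALSE)[, c("first", "second")]
}

#' Classify a label tuple into a relation class
#'
#' @param first Label of the first edge: `"SUBSET"`, `"SUPERSET"` or
#'   `"COORD"`.
#' @param second Label of the second edge, or `"NULL"` (or `NULL`) for a
#'   direct association.
#' @param table Production-rule table; defaults to [production_table()].
#'   Supplying an alternative 12-row table swaps the rule set.
#' @return One of `"SET_SUPERSET"`, `"SUPERSET_SET"`, `"COORDINATE"`,
#'   `"AMBIGUOUS"`.
#' @examples
#' classify_tuple("SUBSET", "NULL")    # SET_SUPERSET
#' classify_tuple("COORD", "COORD")    # COORDINATE
#' classify_tuple("SUBSET", "SUPERSET")  # AMBIGUOUS
#' @export
classify_tuple <- function(first, second = "NULL", table = production_table()) {
  if (is.null(second)) second <- "NULL"
  stopifnot(first %in% .relation_labels,
            second %in% c(.relation_labels, "NULL"))
  hit <- table$class[table$first == first & table$second == second]
  if (length(hit) != 1L)
    stop("production table does not define tuple (", first, ", ", second, ")")
  hit
}

#' Mirror a label tuple from the predicate's point of view
#'
#' A path retrieved from the predicate term is read back-to-front before
#' classification: the edge order is reversed and SUBSET and SUPERSET are
#' swapped (COORD is its own mirror). A single-edge tuple keeps `"NULL"`
#' in second position.
#'
#' @param first,second Labels as in [classify_tuple()].
#' @return A list with elements `first` and `second`.
#' @export
mirror_tuple <- function(first, second = "NULL") {
  if (is.null(second)) second <- "NULL"
  flip <- function(l) switch(l, SUBSET = "SUPERSET", SUPERSET = "SUBSET", l)
  if (second == "NULL") list(first = flip(first), second = "NULL")
  else list(first = flip(second), second = flip(first))
}

#' Label tuple of an associative path
#'
#' @param path A path as returned by [enumerate_paths()].
#' @return List with `first` and `second` labels.
#' @export
path_tuple <- function(path) {
  labs <- path$labels
  list(first = labs[[1L]],
       second = if (length(labs) >= 2L) labs[[2L]] else "NULL")
}
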