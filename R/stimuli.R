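#' Stimulus-list construction
#'
#' Builders for the true and false stimulus lists of the two blocked
#' false-context designs. True lists pair each category's designated
#' typical and atypical exemplar. False lists follow the construction
#' rules of their type, always using each predicate term in exactly two
#' items (paralleling the true lists). "Judged semantically unrelated" is
#' operationalised as: no network path of two or fewer edges AND feature
#' overlap below the taxonomy's `unrelated_threshold`.
#'
#' @name stimulus-lists
NULL

stim_row <- function(list_id, item_id, subject, predicate, stimulus_type,
                     category = NA_character_) {
  data.frame(list_id = list_id, item_id = item_id, subject = subject,
             predicate = predicate, stimulus_type = stimulus_type,
             truth = stimulus_type %in% c("typical_true", "atypical_true"),
             category = category, stringsAsFactors = FALSE)
}

#' Build true stimulus lists
#'
#' Randomly partitions categories into lists; each category contributes
#' one typical and one atypical item, so a list of `categories_per_list`
#' categories holds `2 * categories_per_list` items.
#'
#' @param taxonomy A [generate_taxonomy()] result.
#' @param n_lists Number of lists.
#' @param categories_per_list Categories per list.
#' @param categories Optional pool of category identifiers to draw from
#'   (defaults to all).
#' @return Data frame of items with a `list_id` column.
#' @export
build_true_lists <- function(taxonomy, n_lists = 4L,
                             categories_per_list = 20L,
                             categories = NULL) {
  pool <- if (is.null(categories)) taxonomy$categories$category else categories
  need <- n_lists * categories_per_list
  if (length(pool) < need)
    stop("need ", need, " categories for ", n_lists, " true lists, have ",
         length(pool))
  chosen <- sample(pool, need)
  assign <- rep(seq_len(n_lists), each = categories_per_list)
  ex <- taxonomy$exemplars
  out <- lapply(seq_along(chosen), function(i) {
    cat_w <- chosen[i]
    typ <- ex$word[ex$category == cat_w & ex$role == "true_typical"]
    atyp <- ex$word[ex$category == cat_w & ex$role == "true_atypical"]
    rbind(stim_row(assign[i], paste0("T", cat_w, "t"), typ, cat_w,
                   "typical_true", cat_w),
          stim_row(assign[i], paste0("T", cat_w, "a"), atyp, cat_w,
                   "atypical_true", cat_w))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# TRUE if the pair counts as semantically unrelated under the taxonomy's
# operationalisation.
is_unrelated <- function(taxonomy, a, b) {
  if (feature_overlap(taxonomy, a, b) >= taxonomy$config$unrelated_threshold)
    return(FALSE)
  length(enumerate_paths(taxonomy$network, a, b, max_len = 2L)) == 0L
}

#' Build one false stimulus list
#'
#' Construction rules by type:
#' * `anomalous_false`: predicate is a category term; each subject is an
#'   exemplar of a different-domain category, pair-checked to be
#'   semantically unrelated.
#' * `coordinate_false`: three exemplars of one category; two serve as
#'   subjects, the third as the shared predicate.
#' * `cross_category_false`: predicate is a category term; subjects are
#'   two exemplars of a same-domain coordinate category.
#' * `reversed_false`: predicate is a spare exemplar belonging to two
#'   categories (never used in true items); its two parent categories
#'   serve as subjects.
#'
#' Every predicate term appears in exactly two items.
#'
#' @param type One of the four false types above.
#' @param taxonomy A [generate_taxonomy()] result.
#' @param n_items Number of items (even; `n_items / 2` predicates).
#' @param list_id List identifier stored on the rows.
#' @param exclude_words Terms that must not appear (e.g. practice terms).
#' @param categories Optional pool of category identifiers all terms must
#'   come from.
#' @param max_tries Resampling bound before the constraint is declared
#'   unsatisfiable.
#' @return Data frame of items.
#' @export
build_false_list <- function(type, taxonomy, n_items = 40L, list_id = 1L,
                             exclude_words = character(),
                             categories = NULL, max_tries = 2000L) {
  stopifnot(type %in% c("anomalous_false", "coordinate_false",
                        "cross_category_false", "reversed_false"),
            n_items %% 2L == 0L)
  n_pred <- n_items %/% 2L
  cats <- taxonomy$categories
  ex <- taxonomy$exemplars
  if (!is.null(categories)) {
    cats <- cats[cats$category %in% categories, , drop = FALSE]
    ex <- ex[ex$category %in% categories &
               (is.na(ex$second_parent) |
                  ex$second_parent %in% categories), , drop = FALSE]
  }
  ok_word <- function(w) !w %in% exclude_words
  rows <- list()
  used_pred <- character()

  add_pair <- function(s1, s2, pred, category = NA_character_) {
    k <- length(rows)
    rows[[k + 1L]] <<- stim_row(list_id, sprintf("F%s_%02da", type, k %/% 2L + 1L),
                                s1, pred, type, category)
    rows[[k + 2L]] <<- stim_row(list_id, sprintf("F%s_%02db", type, k %/% 2L + 1L),
                                s2, pred, type, category)
    used_pred <<- c(used_pred, pred)
  }

  tries <- 0L
  while (length(rows) < n_items) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not satisfy the construction constraint for ", type,
           " after ", max_tries, " tries")
    if (type == "anomalous_false") {
      pci <- sample.int(nrow(cats), 1L)
      pred <- cats$category[pci]
      if (!ok_word(pred) || pred %in% used_pred) next
      other <- which(cats$domain != cats$domain[pci])
      sci <- sample(other, 2L)
      subs <- vapply(sci, function(ci) {
        cand <- ex$word[ex$category == cats$category[ci]]
        cand[sample.int(length(cand), 1L)]
      }, character(1))
      if (!all(vapply(subs, ok_word, logical(1)))) next
      if (subs[1L] == subs[2L]) next
      if (!is_unrelated(taxonomy, subs[1L], pred) ||
            !is_unrelated(taxonomy, subs[2L], pred)) next
      add_pair(subs[1L], subs[2L], pred)
    } else if (type == "coordinate_false") {
      ci <- sample.int(nrow(cats), 1L)
      cat_w <- cats$category[ci]
      spare <- ex$word[ex$category == cat_w & ex$role == "spare"]
      if (length(spare) < 3L) next
      trio <- sample(spare, 3L)
      if (!all(vapply(trio, ok_word, logical(1)))) next
      if (trio[3L] %in% used_pred) next
      add_pair(trio[1L], trio[2L], trio[3L], cat_w)
    } else if (type == "cross_category_false") {
      pci <- sample.int(nrow(cats), 1L)
      pred <- cats$category[pci]
      if (!ok_word(pred) || pred %in% used_pred) next
      sibs <- which(cats$domain == cats$domain[pci] &
                      cats$category != pred)
      if (!length(sibs)) next
      sci <- sibs[sample.int(length(sibs), 1L)]
      cand <- ex$word[ex$category == cats$category[sci]]
      if (length(cand) < 2L) next
      subs <- sample(cand, 2L)
      if (!all(vapply(subs, ok_word, logical(1)))) next
      add_pair(subs[1L], subs[2L], pred, cats$category[sci])
    } else { # reversed_false
      two <- which(!is.na(ex$second_parent) & ex$role == "spare")
      if (!length(two))
        stop("taxonomy has no two-category exemplars for reversed items")
      i <- two[sample.int(length(two), 1L)]
      pred <- ex$word[i]
      if (!ok_word(pred) || pred %in% used_pred) next
      parents <- c(ex$category[i], ex$second_parent[i])
      if (!all(vapply(parents, ok_word, logical(1)))) next
      add_pair(parents[1L], parents[2L], pred)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Derive an anomalous list by re-pairing an existing list
#'
#' Randomly re-pairs the subject and predicate terms of the input items
#' under the restrictions that no output pair equals an input pair and
#' every output pair is semantically unrelated (no two-edge network path,
#' feature overlap below threshold). The multisets of subjects and of
#' predicates are preserved exactly.
#'
#' @param items Data frame of stimuli with `subject` and `predicate`.
#' @param taxonomy A [generate_taxonomy()] result.
#' @param type_out Stimulus type stamped on the derived items
#'   (`"cat_derived_anom"` or `"coord_derived_anom"`).
#' @param list_id List identifier for the derived list.
#' @param max_tries Number of shuffle attempts before failing.
#' @return Data frame of derived items.
#' @export
derive_anomalous <- function(items, taxonomy, type_out = "cat_derived_anom",
                             list_id = 1L, max_tries = 400L) {
  stopifnot(nrow(items) %% 2L == 0L,
            type_out %in% c("cat_derived_anom", "coord_derived_anom"))
  n <- nrow(items)
  orig <- paste(items$subject, items$predicate, sep = "\r")
  ok_pair <- function(s, p)
    s != p && !paste(s, p, sep = "\r") %in% orig && is_unrelated(taxonomy, s, p)
  # random re-pairing followed by pairwise swap repair of violations
  pred <- items$predicate[sample.int(n)]
  for (sweep in seq_len(max_tries)) {
    bad <- which(!vapply(seq_len(n), function(i)
      ok_pair(items$subject[i], pred[i]), logical(1)))
    if (!length(bad)) {
      out <- stim_row(list_id, sprintf("D%s_%02d", type_out, seq_len(n)),
                      items$subject, pred, type_out)
      return(out)
    }
    for (i in bad) {
      for (j in sample.int(n, min(n, 25L))) {
        if (j == i) next
        if (ok_pair(items$subject[i], pred[j]) &&
              ok_pair(items$subject[j], pred[i])) {
          tmp <- pred[i]
          pred[i] <- pred[j]
          pred[j] <- tmp
          break
        }
      }
    }
  }
  stop("no valid re-pairing found after ", max_tries, " repair sweeps")
}

#' Swap subjects to form less-similar coordinate pairs
#'
#' Input rows must come in quadruple-defining pairs from one category:
#' (A-B, C-D) with A,B a typical pair and C,D an atypical pair. The swap
#' interchanges the subject terms, producing (A-D, C-B). Applying it
#' twice restores the original pairs.
#'
#' @param pairs Data frame with `subject`, `predicate`, `category`;
#'   consecutive row pairs must share a category.
#' @return Data frame of the same shape with subjects interchanged and
#'   `stimulus_type` toggled between `similar_coord` and
#'   `less_similar_coord`.
#' @export
swap_less_similar <- function(pairs) {
  n <- nrow(pairs)
  if (n %% 2L != 0L)
    stop("input must hold an even number of rows (A-B, C-D quadruples)")
  odd <- seq(1L, n, by = 2L)
  if (!all(pairs$category[odd] == pairs$category[odd + 1L]))
    stop("consecutive rows must pair items from the same category")
  out <- pairs
  out$subject[odd] <- pairs$subject[odd]       # A stays with...
  out$predicate[odd] <- pairs$predicate[odd + 1L]   # ...D
  out$subject[odd + 1L] <- pairs$subject[odd + 1L]  # C stays with...
  out$predicate[odd + 1L] <- pairs$predicate[odd]   # ...B
  if ("stimulus_type" %in% names(out))
    out$stimulus_type <- ifelse(pairs$stimulus_type == "similar_coord",
                                "less_similar_coord", "similar_coord")
  out
}
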