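#' Build the full stimulus set for one experiment
#'
#' Assembles every list the design needs from one synthetic taxonomy:
#' true lists, false lists of each type, derived anomalous lists (second
#' design only) and practice items. A block of categories is reserved for
#' practice so that no practice term appears in any test stimulus.
#'
#' Design 1 ("EXP1"): four 40-item true lists (20 categories each) and two
#' 40-item false lists per type (anomalous, coordinate, cross-category,
#' reversed). Design 2 ("EXP2"): two 80-item true lists, four coordinate
#' lists of 20 more-similar plus 20 less-similar coordinate pairs, two
#' category-derived anomalous lists per true list and one
#' coordinate-derived anomalous list per coordinate list.
#'
#' @param taxonomy A [generate_taxonomy()] result.
#' @param experiment `"EXP1"` or `"EXP2"`.
#' @param n_practice_categories Categories reserved for practice items.
#' @param seed Optional integer seed.
#' @return A list of class `stimulus_set`.
#' @export
build_stimulus_set <- function(taxonomy, experiment = c("EXP1", "EXP2"),
                               n_practice_categories = 24L, seed = NULL) {
  experiment <- match.arg(experiment)
  if (!is.null(seed)) set.seed(seed)
  cats <- taxonomy$categories$category
  nc <- length(cats)
  # reserve whole domains at the tail so practice false items can be
  # built entirely inside the reserved block
  practice_pool <- cats[(nc - n_practice_categories + 1L):nc]
  test_pool <- setdiff(cats, practice_pool)
  ex <- taxonomy$exemplars
  words_of <- function(catset)
    c(catset, ex$word[ex$category %in% catset |
                        (!is.na(ex$second_parent) &
                           ex$second_parent %in% catset)])
  practice_words <- words_of(practice_pool)
  test_words <- words_of(test_pool)

  false_types <- c("anomalous_false", "coordinate_false",
                   "cross_category_false", "reversed_false")
  out <- list(experiment = experiment, taxonomy_config = taxonomy$config)

  if (experiment == "EXP1") {
    out$true <- build_true_lists(taxonomy, 4L, 20L, categories = test_pool)
    out$false <- lapply(stats::setNames(false_types, false_types),
                        function(tp) {
      do.call(rbind, lapply(1:2, function(l)
        build_false_list(tp, taxonomy, 40L, list_id = l,
                         exclude_words = practice_words,
                         categories = test_pool)))
    })
  } else {
    out$true <- build_true_lists(taxonomy, 2L, 40L, categories = test_pool)
    # coordinate quadruples: per category A-B (typical pair) and C-D
    # (atypical pair) are the more-similar items; swapping subjects gives
    # the less-similar items A-D and C-B
    quad_cats <- sample(setdiff(test_pool,
                                unique(out$true$category)), 40L)
    coord_lists <- lapply(1:4, function(l) {
      lc <- quad_cats[((l - 1L) * 10L + 1L):(l * 10L)]
      sim <- do.call(rbind, lapply(lc, function(cw) {
        sp <- ex[ex$category == cw & ex$role == "spare", ]
        typ <- sp$word[sp$typical][1:2]
        atyp <- sp$word[!sp$typical][1:2]
        if (anyNA(c(typ, atyp)))
          stop("category ", cw, " lacks two typical and two atypical spares")
        rbind(stim_row(l, paste0("S", cw, "t"), typ[1L], typ[2L],
                       "similar_coord", cw),
              stim_row(l, paste0("S", cw, "a"), atyp[1L], atyp[2L],
                       "similar_coord", cw))
      }))
      less <- swap_less_similar(sim)
      less$item_id <- sub("^S", "L", less$item_id)
      rbind(sim, less)
    })
    out$false <- list(coordinate = coord_lists)
    # category-derived anomalous: two 40-item lists per true list
    out$false$cat_derived <- lapply(1:2, function(tl) {
      items <- out$true[out$true$list_id == tl, ]
      der <- derive_anomalous(items, taxonomy, "cat_derived_anom",
                              list_id = tl)
      half <- nrow(der) %/% 2L
      list(a = der[seq_len(half), ], b = der[(half + 1L):nrow(der), ])
    })
    # coordinate-derived anomalous: one list per coordinate list
    out$false$coord_derived <- lapply(1:4, function(l)
      derive_anomalous(coord_lists[[l]], taxonomy, "coord_derived_anom",
                       list_id = l))
  }

  # practice: true items plus same-type false items, all inside the
  # reserved categories
  prac_true <- build_true_lists(taxonomy, 1L, 5L, categories = practice_pool)
  prac_false_types <- if (experiment == "EXP1") false_types
  else c("anomalous_false", "coordinate_false")
  out$practice <- lapply(stats::setNames(prac_false_types, prac_false_types),
                         function(tp) {
    pf <- build_false_list(tp, taxonomy, 10L, list_id = 0L,
                           exclude_words = test_words,
                           categories = practice_pool)
    rbind(prac_true, pf)
  })
  structure(out, class = "stimulus_set")
}

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

condition_of_type <- function(tp) {
  switch(tp,
         anomalous_false = "ANOMALOUS",
         coordinate_false = "COORDINATE",
         cross_category_false = "CROSS_CATEGORY",
         reversed_false = "REVERSED")
}

design_rows <- function(participant, block, condition, true_list, false_list,
                        items, practice) {
  data.frame(participant = participant, block = block, condition = condition,
             true_list = true_list, false_list = false_list,
             trial = seq_len(nrow(items)), practice = practice,
             subject = items$subject, predicate = items$predicate,
             stimulus_type = items$stimulus_type, truth = items$truth,
             item_id = items$item_id, stringsAsFactors = FALSE)
}

#' Build a trial-level experiment design
#'
#' For design 1: every participant serves in all four false-context
#' conditions in one of the 4! block orders, each order used exactly once
#' per group of 24 participants; true lists rotate so each list is used
#' equally often with each condition across participants, and each of the
#' two false lists per type is used for half the participants. Each block
#' holds 20 practice trials then 80 test trials (20 typical true, 20
#' atypical true, 40 false) in fresh random order per participant.
#'
#' For design 2: two conditions (Anomalous, Coordinate) of 160 test
#' trials each (80 true, 40 category-derived anomalous, 40 coordinate or
#' coordinate-derived anomalous), preceded by 20 practice trials;
#' condition order, true-list assignment and derived-list assignment are
#' counterbalanced, a participant never sees the same true list twice,
#' and the category-derived list used in a condition is never derived
#' from that condition's true list.
#'
#' @param experiment `"EXP1"` or `"EXP2"`.
#' @param n_participants For `"EXP1"` a multiple of 24 (unless
#'   `allow_any`); 32 is the reference size for `"EXP2"`.
#' @param stimset A [build_stimulus_set()] result for the same experiment.
#' @param seed Optional integer seed for the per-participant trial orders.
#' @param allow_any Permit EXP1 participant counts that are not multiples
#'   of 24 (the orderings then cycle).
#' @return A data frame with one row per trial.
#' @export
make_experiment_design <- function(experiment = c("EXP1", "EXP2"),
                                   n_participants = if (experiment == "EXP1")
                                     24L else 32L,
                                   stimset, seed = NULL, allow_any = FALSE) {
  experiment <- match.arg(experiment)
  stopifnot(inherits(stimset, "stimulus_set"),
            identical(stimset$experiment, experiment))
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_participants)

  if (experiment == "EXP1") {
    if (n_participants %% 24L != 0L && !allow_any)
      stop("EXP1 counterbalancing needs a multiple of 24 participants ",
           "(use allow_any = TRUE to override)")
    conds <- c("ANOMALOUS", "COORDINATE", "CROSS_CATEGORY", "REVERSED")
    types <- c("anomalous_false", "coordinate_false",
               "cross_category_false", "reversed_false")
    perms <- all_perms(4L)
    for (p in seq_len(n_participants)) {
      cond_order <- conds[perms[((p - 1L) %% 24L) + 1L, ]]
      fl <- ((p - 1L) %% 2L) + 1L
      blocks <- lapply(seq_along(cond_order), function(b) {
        cond <- cond_order[b]
        ci <- match(cond, conds)
        tl <- ((p - 1L) + (ci - 1L)) %% 4L + 1L
        test <- rbind(
          stimset$true[stimset$true$list_id == tl, ],
          stimset$false[[types[ci]]][
            stimset$false[[types[ci]]]$list_id == fl, ])
        test <- test[sample.int(nrow(test)), ]
        prac <- stimset$practice[[types[ci]]]
        prac <- prac[sample.int(nrow(prac)), ]
        rbind(design_rows(p, b, cond, tl, fl, prac, TRUE),
              design_rows(p, b, cond, tl, fl, test, FALSE))
      })
      out[[p]] <- do.call(rbind, blocks)
    }
  } else {
    for (p in seq_len(n_participants)) {
      anom_first <- (p %% 2L) == 1L
      tl_anom <- if (((p - 1L) %/% 2L) %% 2L == 0L) 1L else 2L
      tl_coord <- 3L - tl_anom
      derived_half <- if (((p - 1L) %/% 4L) %% 2L == 0L) "a" else "b"
      coord_list <- ((p - 1L) %% 4L) + 1L
      cd_list <- ((p + 1L) %% 4L) + 1L
      build_cond <- function(cond, b) {
        tl <- if (cond == "ANOMALOUS") tl_anom else tl_coord
        cat_der <- stimset$false$cat_derived[[3L - tl]][[derived_half]]
        other <- if (cond == "COORDINATE")
          stimset$false$coordinate[[coord_list]]
        else stimset$false$coord_derived[[cd_list]]
        test <- rbind(stimset$true[stimset$true$list_id == tl, ],
                      cat_der, other)
        test <- test[sample.int(nrow(test)), ]
        ptype <- if (cond == "COORDINATE") "coordinate_false"
        else "anomalous_false"
        prac <- stimset$practice[[ptype]]
        prac <- prac[sample.int(nrow(prac)), ]
        fl <- if (cond == "COORDINATE") coord_list else cd_list
        rbind(design_rows(p, b, cond, tl, fl, prac, TRUE),
              design_rows(p, b, cond, tl, fl, test, FALSE))
      }
      cond_order <- if (anom_first) c("ANOMALOUS", "COORDINATE")
      else c("COORDINATE", "ANOMALOUS")
      out[[p]] <- rbind(build_cond(cond_order[1L], 1L),
                        build_cond(cond_order[2L], 2L))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
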