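small_tax <- function(...) {
  generate_taxonomy(taxonomy_config(n_categories = 24L,
                                    exemplars_per_category = 6L,
                                    seed = 99L, ...))
}

test_that("sparseness controls work as advertised", {
  # without direct links every atypical true exemplar reaches its
  # category only through a two-step coordinate route
  tax <- small_tax(p_atypical_direct_link = 0,
                   p_miswired_subset = 0, p_second_parent = 0)
  atyps <- tax$exemplars[tax$exemplars$role == "true_atypical", ]
  for (i in seq_len(nrow(atyps))) {
    paths <- enumerate_paths(tax$network, atyps$word[i], atyps$category[i],
                             2L)
    expect_gt(length(paths), 0L)
    expect_true(all(vapply(paths, function(p)
      length(p$labels) == 2L, logical(1))))
  }
  # without boundary violations no exemplar reaches a foreign category
  tax2 <- small_tax(p_cross_category_coord = 0, p_miswired_subset = 0,
                    p_second_parent = 0)
  set.seed(1)
  ex <- tax2$exemplars
  for (rep in seq_len(60L)) {
    i <- sample.int(nrow(ex), 1L)
    other <- sample(setdiff(tax2$categories$category, ex$category[i]), 1L)
    expect_length(enumerate_paths(tax2$network, ex$word[i], other, 2L), 0L)
  }
})

test_that("taxonomy generation is deterministic and overlaps are graded", {
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_network_tsv(small_tax()$network, f1)
  write_network_tsv(small_tax()$network, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(generate_taxonomy(taxonomy_config(exemplars_per_category = 2L)),
               "3")

  tax <- shared_taxonomy()
  mean_overlap <- function(items) mean(mapply(
    function(s, p) feature_overlap(tax, s, p), items$subject,
    items$predicate))
  ss <- shared_exp1_stimset()
  ov <- c(typ = mean_overlap(ss$true[ss$true$stimulus_type == "typical_true", ]),
          atyp = mean_overlap(ss$true[ss$true$stimulus_type == "atypical_true", ]),
          coord = mean_overlap(ss$false$coordinate_false),
          rev = mean_overlap(ss$false$reversed_false),
          cross = mean_overlap(ss$false$cross_category_false),
          anom = mean_overlap(ss$false$anomalous_false))
  expect_true(ov["typ"] > ov["atyp"])
  expect_true(ov["atyp"] > ov["coord"] && ov["atyp"] > ov["rev"])
  expect_true(ov["coord"] > ov["cross"] && ov["rev"] > ov["cross"])
  expect_true(ov["cross"] > ov["anom"])
})

test_that("true lists partition categories into typical/atypical pairs", {
  tax <- shared_taxonomy()
  set.seed(11)
  tl <- build_true_lists(tax, 4L, 20L)
  expect_equal(nrow(tl), 160L)
  expect_equal(as.vector(table(tl$list_id)), rep(40L, 4L))
  expect_equal(sum(tl$stimulus_type == "typical_true"), 80L)
  per_cat <- table(tl$category)
  expect_true(all(per_cat == 2L))
  expect_equal(length(unique(tl$category)), 80L)
  one <- build_true_lists(tax, 1L, 20L)
  expect_equal(nrow(one), 40L)
  expect_error(build_true_lists(tax, 10L, 20L), "categories")
})

test_that("false lists obey their construction rules", {
  tax <- shared_taxonomy()
  ss <- shared_exp1_stimset()
  for (tp in names(ss$false)) {
    fl <- ss$false[[tp]]
    expect_equal(nrow(fl), 80L)
    expect_true(all(!fl$truth))
    # each predicate term used in exactly two items within a list
    for (l in unique(fl$list_id))
      expect_true(all(table(fl$predicate[fl$list_id == l]) == 2L))
  }
  # coordinate items pair members of one category
  co <- ss$false$coordinate_false
  ex <- tax$exemplars
  expect_true(all(ex$category[match(co$subject, ex$word)] ==
                    ex$category[match(co$predicate, ex$word)]))
  # anomalous items have no two-edge path between their terms
  an <- ss$false$anomalous_false
  for (i in seq_len(nrow(an)))
    expect_length(enumerate_paths(tax$network, an$subject[i],
                                  an$predicate[i], 2L), 0L)
  # reversed items put a two-category exemplar in predicate position
  rv <- ss$false$reversed_false
  expect_true(all(rv$predicate %in% ex$word[!is.na(ex$second_parent)]))
  expect_true(all(rv$subject %in% tax$categories$category))
})

test_that("derived anomalous lists re-pair without leaving relations", {
  tax <- shared_taxonomy()
  set.seed(13)
  items <- build_true_lists(tax, 1L, 20L)
  der <- derive_anomalous(items, tax, "cat_derived_anom")
  expect_equal(sort(der$subject), sort(items$subject))
  expect_equal(sort(der$predicate), sort(items$predicate))
  expect_length(intersect(paste(der$subject, der$predicate),
                          paste(items$subject, items$predicate)), 0L)
  for (i in seq_len(nrow(der)))
    expect_length(enumerate_paths(tax$network, der$subject[i],
                                  der$predicate[i], 2L), 0L)
  expect_true(all(der$stimulus_type == "cat_derived_anom"))
})

test_that("the less-similar swap interchanges partners and inverts itself", {
  quad <- data.frame(subject = c("washer", "television"),
                     predicate = c("dryer", "stereo"),
                     category = "appliance",
                     stimulus_type = "similar_coord",
                     stringsAsFactors = FALSE)
  swapped <- swap_less_similar(quad)
  expect_equal(swapped$subject, c("washer", "television"))
  expect_equal(swapped$predicate, c("stereo", "dryer"))
  expect_true(all(swapped$stimulus_type == "less_similar_coord"))
  back <- swap_less_similar(swapped)
  expect_equal(back$predicate, quad$predicate)
  expect_error(swap_less_similar(quad[1L, , drop = FALSE]), "even")

  ss <- shared_exp2_stimset()
  tax <- shared_taxonomy()
  ex <- tax$exemplars
  less <- ss$false$coordinate[[1L]]
  less <- less[less$stimulus_type == "less_similar_coord", ]
  expect_true(all(ex$category[match(less$subject, ex$word)] ==
                    ex$category[match(less$predicate, ex$word)]))
})

test_that("the blocked design satisfies its counterbalancing constraints", {
  ss <- shared_exp1_stimset()
  d <- make_experiment_design("EXP1", 24L, ss, seed = 17L)
  test <- d[!d$practice, ]
  expect_equal(nrow(test), 24L * 4L * 80L)
  # each participant sees each condition once, in a unique order
  orders <- vapply(split(test, test$participant), function(pt)
    paste(unique(pt$condition[order(pt$block)]), collapse = ">"),
    character(1))
  expect_equal(length(unique(orders)), 24L)
  # block composition: 20 typical true, 20 atypical true, 40 false
  one_block <- test[test$participant == 1L & test$block == 1L, ]
  expect_equal(nrow(one_block), 80L)
  expect_equal(sum(one_block$stimulus_type == "typical_true"), 20L)
  expect_equal(sum(one_block$stimulus_type == "atypical_true"), 20L)
  expect_equal(sum(!one_block$truth), 40L)
  # practice terms never appear among test terms
  prac <- d[d$practice, ]
  expect_length(intersect(c(prac$subject, prac$predicate),
                          c(test$subject, test$predicate)), 0L)
  # each true list pairs with each condition equally often
  cells <- unique(test[, c("participant", "condition", "true_list")])
  expect_true(all(table(cells$condition, cells$true_list) == 6L))
  # each false list serves half the participants
  fcells <- unique(test[, c("participant", "false_list")])
  expect_true(all(table(fcells$false_list) == 12L))
  expect_error(make_experiment_design("EXP1", 10L, ss), "24")

  d2 <- shared_exp2_sim()$design
  t2 <- d2[!d2$practice, ]
  expect_true(all(table(t2$participant, t2$condition) == 160L))
  lists <- unique(t2[, c("participant", "condition", "true_list")])
  per_part <- split(lists$true_list, lists$participant)
  expect_true(all(vapply(per_part, function(v)
    length(unique(v)) == 2L, logical(1))))
})
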