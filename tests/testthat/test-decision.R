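# a small noiseless taxonomy fragment where every stimulus has an
# unambiguous shortest path
policy_net <- function() {
  net <- semantic_network()
  net <- add_association(net, "carrot", "vegetable", "SUBSET", 0.9)
  net <- add_association(net, "vegetable", "carrot", "SUPERSET", 0.9)
  net <- add_association(net, "vision", "smell", "COORD", 0.7)
  net <- add_association(net, "vehicle", "jet", "SUPERSET", 0.8)
  net <- add_association(net, "chicken", "hawk", "COORD", 0.6)
  net <- add_association(net, "hawk", "bird", "SUBSET", 0.8)
  net
}

test_that("the anomalous policy answers from retrieval alone", {
  set.seed(601)
  net <- policy_net()
  r <- decide_network(net, trial_stimulus("carrot", "vegetable",
                                          "typical_true", "ANOMALOUS"))
  expect_true(r$response)
  expect_true(r$correct)
  expect_equal(r$stage2, 0)
  expect_equal(r$mechanism, "NETWORK")
  expect_equal(r$rt, decision_params()$base_time + r$stage1)

  miss <- decide_network(net, trial_stimulus("carrot", "jet",
                                             "anomalous_false", "ANOMALOUS"))
  expect_false(miss$response)
  expect_true(miss$correct)
})

test_that("path evaluation classifies coordinate and reversed falses", {
  set.seed(602)
  net <- policy_net()
  co <- decide_network(net, trial_stimulus("vision", "smell",
                                           "coordinate_false", "COORDINATE"))
  expect_false(co$response)
  expect_true(co$correct)
  expect_equal(co$stage2, decision_params()$eval_time)

  rv <- decide_network(net, trial_stimulus("vehicle", "jet",
                                           "reversed_false", "REVERSED"))
  expect_false(rv$response)
  expect_true(rv$correct)

  # true item via a two-step chain, evaluated from either origin
  for (rep in seq_len(10L)) {
    tr <- decide_network(net, trial_stimulus("chicken", "bird",
                                             "atypical_true", "COORDINATE"))
    expect_true(tr$response)
    expect_gte(tr$stage2, decision_params()$eval_time)
  }
  expect_error(decide_network(net, trial_stimulus("carrot", "fruit",
                                                  "cross_category_false",
                                                  "CROSS_CATEGORY")),
               "feature fallback")
})

test_that("a zero evaluation time collapses evaluation onto retrieval", {
  net <- policy_net()
  d0 <- decision_params(eval_time = 0)
  for (seed in 1:10) {
    set.seed(seed)
    a <- decide_network(net, trial_stimulus("carrot", "vegetable",
                                            "typical_true", "ANOMALOUS"),
                        dparams = d0)
    set.seed(seed)
    b <- decide_network(net, trial_stimulus("carrot", "vegetable",
                                            "typical_true", "COORDINATE"),
                        dparams = d0)
    expect_equal(a$rt, b$rt)
  }
})

test_that("responses match the oracle's shortest-path classification", {
  set.seed(603)
  net <- policy_net()
  cases <- list(
    list("carrot", "vegetable", "COORDINATE"),
    list("vision", "smell", "COORDINATE"),
    list("chicken", "bird", "COORDINATE"),
    list("vehicle", "jet", "REVERSED"),
    list("carrot", "vegetable", "REVERSED"))
  for (cs in cases) {
    paths <- enumerate_paths(net, cs[[1L]], cs[[2L]], 2L)
    lens <- vapply(paths, function(p) length(p$labels), integer(1))
    sp <- paths[[which.min(lens)]]
    want <- classify_tuple(path_tuple(sp)$first,
                           path_tuple(sp)$second) == "SET_SUPERSET"
    for (rep in seq_len(5L)) {
      got <- decide_network(net, trial_stimulus(
        cs[[1L]], cs[[2L]], "typical_true", cs[[3L]]))
      expect_equal(got$response, want,
                   info = paste(cs[[1L]], cs[[2L]], cs[[3L]]))
    }
  }
})

test_that("the feature counter race honours its criteria", {
  set.seed(604)
  fp <- feature_params(c_true = 5L, c_false = 7L, c_true_shifted = 5L)
  sure <- feature_params(overlap_typical = 1 - 1e-12,
                         c_true = 5L, c_false = 7L)
  stim <- trial_stimulus("s", "p", "typical_true", "CROSS_CATEGORY")
  for (rep in seq_len(20L)) {
    r <- feature_verify(stim, sure)
    expect_true(r$response)
    expect_equal(r$stage1, 5 * sure$sample_time)
  }
  none <- feature_params(overlap_typical = 0.9, overlap_atypical = 1e-12,
                         c_true = 5L, c_false = 7L)
  astim <- trial_stimulus("s", "p", "atypical_true", "CROSS_CATEGORY")
  for (rep in seq_len(20L)) {
    r <- feature_verify(astim, none)
    expect_false(r$response)
    expect_equal(r$stage1, 7 * none$sample_time)
  }
  expect_error(feature_params(c_true = 0L), "criteria")
})

test_that("raising the true criterion amplifies the feature typicality gap", {
  set.seed(605)
  gap <- function(ct) {
    typ <- semnetverify:::feature_race(2e4, 0.9, ct, 12L)
    atyp <- semnetverify:::feature_race(2e4, 0.7, ct, 12L)
    mean(atyp$samples) - mean(typ$samples)
  }
  expect_gt(gap(8L), gap(4L))
})

test_that("trial routing picks the mechanism by condition", {
  set.seed(606)
  net <- policy_net()
  cross <- verify_trial(net, trial_stimulus("carrot", "vegetable",
                                            "typical_true", "CROSS_CATEGORY"))
  expect_equal(cross$mechanism, "FEATURE")
  anom <- verify_trial(net, trial_stimulus("carrot", "vegetable",
                                           "typical_true", "ANOMALOUS"))
  expect_equal(anom$mechanism, "NETWORK")
  expect_equal(anom$stage2, 0)
  run_seeded <- function() {
    set.seed(42)
    verify_trial(net, trial_stimulus("chicken", "bird", "atypical_true",
                                     "COORDINATE"))
  }
  expect_identical(run_seeded(), run_seeded())
})

test_that("evaluation duration is independent of typicality", {
  # two-item network: typical with a strong direct link, atypical with a
  # weak one; both decided by a single unambiguous evaluation
  set.seed(607)
  net <- semantic_network()
  net <- add_association(net, "typ", "cat", "SUBSET", 0.8)
  net <- add_association(net, "atyp", "cat", "SUBSET", 0.4)
  s2 <- function(s, type) replicate(2000L, decide_network(
    net, trial_stimulus(s, "cat", type, "COORDINATE"))$stage2)
  typ <- s2("typ", "typical_true")
  atyp <- s2("atyp", "atypical_true")
  expect_equal(mean(typ), mean(atyp))  # exactly equal: no ambiguous paths
  expect_equal(unique(typ), decision_params()$eval_time)
})
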