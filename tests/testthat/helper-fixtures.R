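# Shared fixtures, built lazily once per test session.

.shared <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.shared[[key]])) .shared[[key]] <- build()
  .shared[[key]]
}

# the three-word indirect-membership example network
chicken_net <- function() {
  net <- semantic_network()
  net <- add_association(net, "chicken", "hawk", "COORD", 0.6)
  add_association(net, "hawk", "bird", "SUBSET", 0.8)
}

# random directed labeled network for property tests
random_net <- function(n_words = 20L, n_edges = 60L) {
  words <- sprintf("w%02d", seq_len(n_words))
  src <- sample(words, 4L * n_edges, replace = TRUE)
  tgt <- sample(words, 4L * n_edges, replace = TRUE)
  lab <- sample(c("SUBSET", "SUPERSET", "COORD"), 4L * n_edges,
                replace = TRUE)
  ok <- src != tgt & !duplicated(paste(src, tgt, lab))
  keep <- which(ok)[seq_len(min(n_edges, sum(ok)))]
  edges <- data.frame(source = src[keep], target = tgt[keep],
                      label = lab[keep],
                      strength = round(runif(length(keep), 0.05, 1), 3),
                      stringsAsFactors = FALSE)
  semantic_network(words = words, edges = edges, coord_symmetric = FALSE)
}

# independent brute-force path oracle: explicit edge-table joins per
# depth, no recursion shared with the package implementation
oracle_paths <- function(net, origin, target, max_len) {
  e <- net$edges
  out <- list()
  d1 <- e[e$source == origin & e$target == target, , drop = FALSE]
  for (i in seq_len(nrow(d1)))
    out[[length(out) + 1L]] <- list(words = c(origin, target),
                                    labels = d1$label[i])
  if (max_len >= 2L) {
    e1 <- e[e$source == origin & e$target != target & e$target != origin, ,
            drop = FALSE]
    for (i in seq_len(nrow(e1))) {
      mid <- e1$target[i]
      e2 <- e[e$source == mid & e$target == target, , drop = FALSE]
      for (j in seq_len(nrow(e2)))
        out[[length(out) + 1L]] <- list(words = c(origin, mid, target),
                                        labels = c(e1$label[i], e2$label[j]))
    }
  }
  if (max_len >= 3L) {
    e1 <- e[e$source == origin & !e$target %in% c(target, origin), ,
            drop = FALSE]
    for (i in seq_len(nrow(e1))) {
      m1 <- e1$target[i]
      e2 <- e[e$source == m1 & !e$target %in% c(target, origin, m1), ,
              drop = FALSE]
      for (j in seq_len(nrow(e2))) {
        m2 <- e2$target[j]
        e3 <- e[e$source == m2 & e$target == target, , drop = FALSE]
        for (k in seq_len(nrow(e3)))
          out[[length(out) + 1L]] <- list(
            words = c(origin, m1, m2, target),
            labels = c(e1$label[i], e2$label[j], e3$label[k]))
      }
    }
  }
  out
}

path_signature <- function(p) paste(c(p$words, p$labels), collapse = "|")

signatures <- function(paths)
  sort(vapply(paths, path_signature, character(1)))

shared_taxonomy <- function() memo("taxonomy", function()
  generate_taxonomy(taxonomy_config(seed = 42L)))

shared_exp1_stimset <- function() memo("stimset1", function() {
  build_stimulus_set(shared_taxonomy(), "EXP1", seed = 7L)
})

shared_exp2_stimset <- function() memo("stimset2", function() {
  build_stimulus_set(shared_taxonomy(), "EXP2", seed = 7L)
})

shared_exp1_sim <- function() memo("sim1", function()
  run_pipeline(run_config("EXP1", 24L, master_seed = 1L)))

shared_exp2_sim <- function() memo("sim2", function() {
  tax <- shared_taxonomy()
  design <- make_experiment_design("EXP2", 16L, shared_exp2_stimset(),
                                   seed = 3L)
  list(design = design,
       trials = run_experiment(design, tax, seed = 5L))
})
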