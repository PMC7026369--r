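#' Configuration of the synthetic taxonomy generator
#'
#' The generator emulates the structural facts the network model trades
#' on: graded association strength (typical exemplars hold strong direct
#' SUBSET links, atypical exemplars hold weaker ones or none), sparseness
#' (an atypical exemplar may reach its category only through a COORD link
#' to a typical sibling), occasional category-boundary violations
#' (mis-wired SUBSET edges, cross-category COORD edges), and feature
#' vectors whose pairwise overlap decreases from typical-true pairs down
#' to anomalous pairs.
#'
#' Categories are grouped into domains of `domain_size`; categories in the
#' same domain are "category coordinates" (fruit/vegetable), which is what
#' cross-category false items exploit.
#'
#' @param n_categories Number of categories in the master taxonomy.
#' @param exemplars_per_category Exemplars per category (>= 3; coordinate
#'   false construction selects three exemplars of one category).
#' @param typical_strength,atypical_strength Direct SUBSET strengths;
#'   `typical_strength > atypical_strength`.
#' @param coord_strength Strength of COORD edges.
#' @param p_atypical_direct_link Probability an atypical exemplar has a
#'   direct SUBSET edge; otherwise it reaches the category only through a
#'   COORD link to a typical sibling.
#' @param coord_density Probability of a COORD edge per within-category
#'   exemplar pair (beyond the guaranteed links).
#' @param p_cross_category_coord Per-pair probability of a COORD edge
#'   between exemplars of different categories.
#' @param p_miswired_subset Probability an exemplar also holds a SUBSET
#'   edge to a same-domain coordinate category (the model's error source).
#' @param p_second_parent Probability a spare exemplar belongs to a second
#'   same-domain category (needed for reversed false items).
#' @param n_features Length of the binary feature vectors.
#' @param domain_size Categories per domain.
#' @param unrelated_threshold Feature-overlap ceiling for two terms to
#'   count as semantically unrelated.
#' @param seed Optional integer seed.
#' @return A list of class `taxonomy_config`.
#' @export
taxonomy_config <- function(n_categories = 164L,
                            exemplars_per_category = 6L,
                            typical_strength = 0.8,
                            atypical_strength = 0.55,
                            coord_strength = 0.4,
                            p_atypical_direct_link = 0.9,
                            coord_density = 0.25,
                            p_cross_category_coord = 5e-4,
                            p_miswired_subset = 0.02,
                            p_second_parent = 0.3,
                            n_features = 60L,
                            domain_size = 4L,
                            unrelated_threshold = 0.55,
                            seed = NULL) {
  stopifnot(n_categories >= 1L, typical_strength > atypical_strength,
            typical_strength <= 1, atypical_strength > 0,
            coord_strength > 0, coord_strength <= 1, domain_size >= 2L)
  probs <- c(p_atypical_direct_link, coord_density, p_cross_category_coord,
             p_miswired_subset, p_second_parent)
  stopifnot(all(probs >= 0 & probs <= 1))
  if (exemplars_per_category < 3L)
    stop("exemplars_per_category must be >= 3 ",
         "(coordinate false items select three exemplars of one category)")
  structure(list(n_categories = as.integer(n_categories),
                 exemplars_per_category = as.integer(exemplars_per_category),
                 typical_strength = typical_strength,
                 atypical_strength = atypical_strength,
                 coord_strength = coord_strength,
                 p_atypical_direct_link = p_atypical_direct_link,
                 coord_density = coord_density,
                 p_cross_category_coord = p_cross_category_coord,
                 p_miswired_subset = p_miswired_subset,
                 p_second_parent = p_second_parent,
                 n_features = as.integer(n_features),
                 domain_size = as.integer(domain_size),
                 unrelated_threshold = unrelated_threshold,
                 seed = seed),
            class = "taxonomy_config")
}

word_id <- function(cat_idx, ex_idx = NULL) {
  if (is.null(ex_idx)) sprintf("c%03d", cat_idx)
  else sprintf("c%03de%d", cat_idx, ex_idx)
}

#' Generate a synthetic taxonomy
#'
#' Builds the semantic network, the category map (category/domain
#' membership, designated typical and atypical true-list exemplars, spare
#' exemplars, second parents) and binary feature vectors for every term.
#'
#' Typical exemplars receive a direct SUBSET edge at `typical_strength`
#' plus the reciprocal SUPERSET; atypical exemplars receive a direct
#' SUBSET at `atypical_strength` with probability `p_atypical_direct_link`
#' and otherwise only a COORD link to a typical sibling. Additional COORD
#' edges are laid down within categories at `coord_density` and across
#' categories at `p_cross_category_coord`; with probability
#' `p_miswired_subset` an exemplar also gains a SUBSET edge to a
#' same-domain coordinate category.
#'
#' @param config A [taxonomy_config()].
#' @return A list of class `taxonomy`: `network` ([semantic_network()]),
#'   `categories` (data frame: category, domain), `exemplars` (data
#'   frame: word, category, typical, role, second_parent), `features`
#'   (0/1 matrix, one row per term), `config`.
#' @export
generate_taxonomy <- function(config = taxonomy_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  nc <- config$n_categories
  ne <- config$exemplars_per_category
  nf <- config$n_features
  domains <- rep(seq_len(ceiling(nc / config$domain_size)),
                 each = config$domain_size)[seq_len(nc)]
  categories <- data.frame(category = word_id(seq_len(nc)), domain = domains,
                           stringsAsFactors = FALSE)

  # roles: e1 designated typical, e2 designated atypical (the true-list
  # pair); remaining spares alternate so every category has both typical
  # and atypical spares for coordinate-false construction.
  typical_flag <- function(i) i == 1L || (i >= 3L && i <= (2L + (ne - 2L) %/% 2L))
  ex <- do.call(rbind, lapply(seq_len(nc), function(ci) {
    data.frame(word = word_id(ci, seq_len(ne)),
               category = word_id(ci),
               typical = vapply(seq_len(ne), typical_flag, logical(1)),
               role = c("true_typical", "true_atypical",
                        rep("spare", ne - 2L)),
               second_parent = NA_character_,
               stringsAsFactors = FALSE)
  }))

  # second parents: spares may belong to a second same-domain category
  for (i in which(ex$role == "spare")) {
    if (stats::runif(1) < config$p_second_parent) {
      ci <- match(ex$category[i], categories$category)
      sibs <- categories$category[categories$domain == categories$domain[ci]]
      sibs <- setdiff(sibs, ex$category[i])
      if (length(sibs))
        ex$second_parent[i] <- sibs[sample.int(length(sibs), 1L)]
    }
  }

  edges <- list()
  push <- function(s, t, l, w)
    edges[[length(edges) + 1L]] <<- data.frame(
      source = s, target = t, label = l, strength = w,
      stringsAsFactors = FALSE)

  for (ci in seq_len(nc)) {
    cat_w <- word_id(ci)
    rows <- ex[ex$category == cat_w, , drop = FALSE]
    typicals <- rows$word[rows$typical]
    for (j in seq_len(nrow(rows))) {
      w <- rows$word[j]
      if (rows$typical[j]) {
        push(w, cat_w, "SUBSET", config$typical_strength)
        push(cat_w, w, "SUPERSET", config$typical_strength)
      } else if (stats::runif(1) < config$p_atypical_direct_link) {
        push(w, cat_w, "SUBSET", config$atypical_strength)
      } else {
        sib <- setdiff(typicals, w)
        sib <- sib[sample.int(length(sib), 1L)]
        push(w, sib, "COORD", config$coord_strength)
      }
      if (!is.na(rows$second_parent[j])) {
        push(w, rows$second_parent[j], "SUBSET", config$atypical_strength)
        push(rows$second_parent[j], w, "SUPERSET", config$atypical_strength)
      }
      if (stats::runif(1) < config$p_miswired_subset) {
        ci_dom <- categories$domain[ci]
        others <- categories$category[categories$domain == ci_dom &
                                        categories$category != cat_w]
        if (length(others))
          push(w, others[sample.int(length(others), 1L)], "SUBSET",
               config$atypical_strength)
      }
    }
    # within-category COORD fabric
    if (nrow(rows) >= 2L && config$coord_density > 0) {
      prs <- utils::combn(rows$word, 2L)
      keep <- stats::runif(ncol(prs)) < config$coord_density
      for (k in which(keep))
        push(prs[1L, k], prs[2L, k], "COORD", config$coord_strength)
    }
  }

  # cross-category COORD edges, sampled at the expected count
  if (config$p_cross_category_coord > 0) {
    all_ex <- ex$word
    n_pairs <- choose(length(all_ex), 2L)
    n_cross <- stats::rbinom(1L, n_pairs, config$p_cross_category_coord)
    tries <- 0L
    added <- 0L
    while (added < n_cross && tries < 20L * n_cross) {
      tries <- tries + 1L
      pick <- sample.int(length(all_ex), 2L)
      if (ex$category[pick[1L]] == ex$category[pick[2L]]) next
      push(all_ex[pick[1L]], all_ex[pick[2L]], "COORD", config$coord_strength)
      added <- added + 1L
    }
  }

  net <- semantic_network(
    words = c(categories$category, ex$word),
    edges = do.call(rbind, edges), coord_symmetric = TRUE)

  features <- make_features(categories, ex, nf, config)

  structure(list(network = net, categories = categories, exemplars = ex,
                 features = features, config = config),
            class = "taxonomy")
}

# Binary feature vectors. Domain base -> category prototype (flip 0.3)
# -> exemplar (flip 0.08 typical, 0.25 atypical; second-parent exemplars
# mix the two parents' prototypes feature-wise with flip 0.15). Category
# terms carry their prototype. Expected pairwise overlaps then order as
# typical-true > atypical-true > reversed ~ coordinate > cross-category
# > anomalous.
make_features <- function(categories, ex, nf, config) {
  n_dom <- max(categories$domain)
  dom_base <- matrix(stats::rbinom(n_dom * nf, 1L, 0.5), nrow = n_dom)
  flip <- function(v, p) {
    f <- stats::runif(length(v)) < p
    ifelse(f, 1L - v, v)
  }
  proto <- t(vapply(seq_len(nrow(categories)), function(ci)
    flip(dom_base[categories$domain[ci], ], 0.3), integer(nf)))
  rownames(proto) <- categories$category
  exf <- t(vapply(seq_len(nrow(ex)), function(i) {
    p1 <- proto[ex$category[i], ]
    if (!is.na(ex$second_parent[i])) {
      p2 <- proto[ex$second_parent[i], ]
      src <- stats::runif(nf) < 0.5
      flip(ifelse(src, p1, p2), 0.15)
    } else {
      flip(p1, if (ex$typical[i]) 0.08 else 0.25)
    }
  }, integer(nf)))
  rownames(exf) <- ex$word
  rbind(proto, exf)
}

#' Feature overlap between two terms
#'
#' Proportion of feature positions on which the two binary vectors agree.
#'
#' @param taxonomy A [generate_taxonomy()] result.
#' @param a,b Term identifiers.
#' @return Overlap in `[0, 1]`.
#' @export
feature_overlap <- function(taxonomy, a, b) {
  f <- taxonomy$features
  if (!a %in% rownames(f)) stop("unknown word: ", a)
  if (!b %in% rownames(f)) stop("unknown word: ", b)
  mean(f[a, ] == f[b, ])
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("Synthetic taxonomy:", nrow(x$categories), "categories x",
      x$config$exemplars_per_category, "exemplars,",
      nrow(x$network$edges), "associations\n")
  invisible(x)
}
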