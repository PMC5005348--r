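test_that("enrichment ratio and Fisher p follow their definitions", {
  u <- sprintf("G%02d", 1:20)
  r <- enrich_term(u[1:8], u[c(1:4, 20)], u)
  expect_equal(r$N, 20); expect_equal(r$B, 5)
  expect_equal(r$n, 8); expect_equal(r$b, 4)
  expect_equal(r$enrichment, 2.0)
  expect_equal(r$p, oracle_hyper_upper(4, 20, 5, 8))
  expect_equal(r$p,
               fisher.test(matrix(c(4, 1, 4, 11), 2),
                           alternative = "greater")$p.value)

  # full enumeration over all 8-subsets of the universe
  subs <- combn(20, 8)
  in_term <- c(1:4, 20)
  tail_mass <- mean(apply(subs, 2, function(s)
    sum(s %in% in_term)) >= 4)
  expect_equal(r$p, tail_mass, tolerance = 1e-12)

  empty <- enrich_term(u[5:10], u[c(1, 2)], u)
  expect_equal(empty$enrichment, 0)
  expect_equal(empty$p, 1)

  expect_error(enrich_term(character(0), u[1:2], u), "empty query")
  expect_error(enrich_term(u[1:3], "NOT_IN_UNIVERSE", u), "empty term")
})

test_that("BY adjustment applies the harmonic-sum step-up", {
  expect_equal(adjust_by(0.2), 0.2)
  expect_equal(adjust_by(c(0.01, 0.5, 0.9)), c(0.055, 1, 1))
  set.seed(3)
  for (i in 1:10) {
    p <- runif(sample(2:40, 1))
    expect_true(all(adjust_by(p) >= adjust_bh(p)))
    expect_true(all(adjust_by(p) <= 1))
  }
  expect_error(adjust_by(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("enrichment filtering applies inclusive and strict bounds", {
  recs <- data.frame(term_id = c("a", "b", "c", "d"),
                     count = c(10, 9, 50, 10),
                     enrichment = c(2.0, 5.0, 1.9, 3.0),
                     fdr = c(0.0999, 0.001, 0.001, 0.10))
  kept <- filter_enriched(recs)
  expect_identical(kept$term_id, "a")  # boundary: 10, 2.0, fdr < 0.10
  expect_identical(filter_enriched(kept), kept)  # idempotent
})

test_that("term collapsing merges through the shared-gene graph", {
  g <- function(n, off = 0) sprintf("D%03d", off + seq_len(n))
  # single term is its own component
  single <- records_from_sets(list(T1 = g(30)))
  expect_equal(nrow(collapse_terms(single)), 1)

  # chain A-B (25 shared), B-C (25 shared), A-C (0 shared) collapses fully
  core_ab <- g(25)
  core_bc <- g(25, 100)
  sets <- list(A = c(core_ab, g(5, 200)),
               B = c(core_ab, core_bc),
               C = c(core_bc, g(5, 300)))
  one <- collapse_terms(records_from_sets(sets))
  expect_equal(nrow(one), 1)
  expect_identical(one$members[[1]], c("A", "B", "C"))
  expect_equal(one$count, length(unique(unlist(sets))))

  # 24 shared genes stay separate
  sets24 <- list(A = c(g(24), g(6, 200)), B = c(g(24), g(6, 300)))
  expect_equal(nrow(collapse_terms(records_from_sets(sets24))), 2)

  # representative carries the smallest FDR, ties broken by id
  two <- records_from_sets(list(X = g(30), Y = g(30)),
                           fdr = c(0.05, 0.001))
  col <- collapse_terms(two)
  expect_identical(col$representative, "Y")
  expect_equal(nrow(collapse_terms(two[0, ])), 0)
})

test_that("collapsing is permutation-invariant and idempotent", {
  set.seed(14)
  genes <- sprintf("D%03d", 1:300)
  for (i in 1:10) {
    n_blocks <- sample(2:4, 1)
    pool <- split(genes, rep(seq_len(n_blocks),
                             length.out = length(genes)))
    sets <- list()
    for (bk in seq_len(n_blocks)) {
      core <- sample(pool[[bk]], 30)
      for (t in 1:sample(1:3, 1)) {
        sets[[sprintf("B%d_T%d", bk, t)]] <-
          unique(c(core, sample(pool[[bk]], 10)))
      }
    }
    recs <- records_from_sets(sets)
    ref <- collapse_terms(recs)
    perm <- collapse_terms(recs[sample(nrow(recs)), , drop = FALSE])
    expect_identical(ref$representative, perm$representative)
    expect_identical(ref$members, perm$members)
    # idempotence: collapsing the collapsed unions changes nothing
    again <- records_from_sets(setNames(ref$genes, ref$representative),
                               fdr = seq_len(nrow(ref)) / 100)
    expect_equal(nrow(collapse_terms(again)), nrow(ref))
    expect_identical(sort(unlist(collapse_terms(again)$genes)),
                     sort(unlist(ref$genes)))
  }
})

test_that("inverse-membership weights sum to the annotated gene count", {
  expect_equal(unname(gene_weights(list(a = "X", b = "X", c = "X",
                                        d = "X"))["X"]), 0.25)
  expect_equal(unname(gene_weights(list(a = "X"))["X"]), 1.0)
  set.seed(15)
  genes <- sprintf("G%03d", 1:100)
  for (i in 1:20) {
    sets <- lapply(seq_len(sample(2:10, 1)), function(j)
      sample(genes, sample(3:30, 1)))
    names(sets) <- paste0("T", seq_along(sets))
    w <- gene_weights(sets)
    term_weights <- vapply(sets, function(s) sum(w[s]), numeric(1))
    expect_equal(sum(term_weights), length(unique(unlist(sets))))
  }
})

test_that("tissue summary computes CNS fractions by set-size mass", {
  uni <- data.frame(term_id = c("brain", "hippocampus", "liver"),
                    B = c(6000, 1858, 21490))
  ts <- tissue_summary(NULL, uni, cns_terms = c("brain", "hippocampus"))
  expect_equal(ts$cns_pct_universe, 27)
  expect_true(is.na(ts$cns_pct_hits))

  all_cns <- data.frame(term_id = c("a", "b"), count = c(5, 7),
                        B = c(10, 20))
  expect_equal(tissue_summary(all_cns, all_cns, c("a", "b"))$cns_pct_hits,
               100)

  set.seed(16)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    recs <- data.frame(term_id = paste0("t", 1:n),
                       count = sample(1:50, n), B = sample(50:500, n))
    cns <- sample(recs$term_id, sample(1:n, 1))
    ts <- tissue_summary(recs, recs, cns)
    expect_equal(ts$cns_pct_hits,
                 round(100 * sum(recs$count[recs$term_id %in% cns]) /
                         sum(recs$count)))
    expect_equal(ts$cns_pct_universe,
                 round(100 * sum(recs$B[recs$term_id %in% cns]) /
                         sum(recs$B)))
  }
})

test_that("planted gene-set structure is recovered end to end", {
  genes <- sprintf("G%04d", 1:1500)
  de <- genes[1:250]
  sim <- simulate_genesets(genes, de, n_background = 5,
                           collapse_blocks = list(
                             list(n_terms = 3, shared_de = 25,
                                  extra_size = 40),
                             list(n_terms = 2, shared_de = 24,
                                  extra_size = 40)),
                           seed = 17)
  recs <- enrich_collection(de, sim$collection)
  b1 <- sim$truth$block_terms[[1]]
  b2 <- sim$truth$block_terms[[2]]
  col <- collapse_terms(recs[recs$term_id %in% c(b1, b2), , drop = FALSE])
  members <- col$members
  expect_true(any(vapply(members, identical, logical(1),
                         sort(b1))))             # 25 shared: one component
  expect_true(all(b2 %in% unlist(members[lengths(members) == 1])))  # 24: apart
})

test_that("Fisher p-values are calibrated on null gene sets", {
  set.seed(18)
  genes <- sprintf("G%04d", 1:2000)
  query <- sample(genes, 360)
  gs <- simulate_genesets(genes, de_genes = character(0),
                          n_background = 500, size_range = c(40, 150),
                          seed = 18)
  recs <- enrich_collection(query, gs$collection)
  frac <- mean(recs$p < 0.05)
  mc_se <- sqrt(0.05 * 0.95 / nrow(recs))
  expect_lt(abs(frac - 0.05), 3 * mc_se + 1e-9)
})
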