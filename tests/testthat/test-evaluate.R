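toy_ann <- function() {
  # 10 proteins; term gA on p1..p4, gB on p1..p2, gCommon on p1..p9
  annotation_map(
    proteins = c(paste0("p", 1:4), "p1", "p2", paste0("p", 1:9)),
    terms = c(rep("gA", 4), rep("gB", 2), rep("gCommon", 9)))
}

test_that("match_score is the Jaccard index with its edge cases", {
  expect_equal(match_score(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(match_score(c("a", "b"), c("c", "d")), 0.0)
  expect_equal(match_score(paste0("x", 1:5), c(paste0("x", 1:4), "y")), 4 / 6)
  expect_equal(match_score("a", "a"), match_score("a", "a"))  # symmetric by def
  expect_error(match_score(character(), "a"), "non-empty")
  # symmetry and bounds on random sets
  withr::local_seed(2)
  for (rep in 1:20) {
    A <- sample(letters, sample(1:10, 1)); B <- sample(letters, sample(1:10, 1))
    expect_equal(match_score(A, B), match_score(B, A))
    expect_gte(match_score(A, B), 0); expect_lte(match_score(A, B), 1)
    expect_equal(match_score(A, B) == 1, setequal(A, B))
  }
})

test_that("count_matches applies the at-least-one-reference rule", {
  ref <- list(r1 = paste0("x", 1:5), r2 = letters[1:3])
  expect_equal(count_matches(list(q = paste0("x", 1:5)), ref), 1L)
  q46 <- list(q = c(paste0("x", 1:4), "zz"))  # overlap 4/6
  expect_equal(count_matches(q46, ref, threshold = 0.5), 1L)
  expect_equal(count_matches(q46, ref, threshold = 0.7), 0L)
  expect_equal(count_matches(q46, list()), 0L)
})

test_that("information content follows -log2 of annotation frequency", {
  ann <- toy_ann()
  expect_equal(information_content("gCommon", ann, universe_size = 9), 0)
  expect_equal(information_content("gA", ann, universe_size = 16), 2.0)
  expect_equal(information_content("gB", ann, universe_size = 2048), 10.0)
  expect_error(information_content("nope", ann), "unknown term")
  # monotone decreasing in term size
  expect_gt(information_content("gB", ann), information_content("gA", ann))
  expect_gt(information_content("gA", ann), information_content("gCommon", ann))
})

test_that("hypergeometric p-values match closed form and brute enumeration", {
  ann <- annotation_map(proteins = paste0("p", 1:5), terms = rep("g", 5))
  bg <- paste0("p", 1:10)
  enr <- enrichment_test(paste0("p", 1:4), ann, background = bg, ic_min = 0)
  expect_equal(enr$p, 5 / 210, tolerance = 1e-12)
  expect_equal(enr$q, enr$p)  # single tested term: BH is the identity

  # brute-force enumeration over all C(N, n) draws, several configurations
  withr::local_seed(31)
  for (rep in 1:6) {
    N <- sample(6:12, 1); K <- sample(2:(N - 1), 1); n <- sample(2:(N - 1), 1)
    bg <- sprintf("u%02d", 1:N)
    ann2 <- annotation_map(bg[1:K], rep("g", K))
    nodes <- sample(bg, n)
    k <- sum(nodes %in% bg[1:K])
    enr2 <- enrichment_test(nodes, ann2, background = bg, ic_min = 0)
    if (k == 0) {
      expect_equal(nrow(enr2), 0L)
    } else {
      expect_equal(enr2$p, oracle_hypergeom_enum(N, K, n, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("the IC filter and overlap filter gate which terms are tested", {
  ann <- toy_ann()  # universe 9: IC(gA)=-log2(4/9)=1.17, IC(gB)=2.17
  enr <- enrichment_test(c("p1", "p2"), ann, ic_min = 2)
  expect_equal(enr$term, "gB")
  enr0 <- enrichment_test(c("p1", "p2"), ann, ic_min = 0)
  expect_setequal(enr0$term, c("gA", "gB", "gCommon"))
  # no overlap anywhere: empty result
  expect_equal(nrow(enrichment_test("p9", ann, ic_min = 2)), 0L)
  expect_error(enrichment_test("p1", ann, background = character()), "empty")
})

test_that("BH q-values are monotone in p-rank and bounded", {
  withr::local_seed(13)
  prot <- sprintf("p%02d", 1:30)
  ann <- annotation_map(
    proteins = sample(prot, 60, replace = TRUE),
    terms = sample(sprintf("g%02d", 1:12), 60, replace = TRUE))
  enr <- enrichment_test(sample(prot, 8), ann, background = prot, ic_min = 0)
  if (nrow(enr) > 1) {
    expect_true(all(diff(enr$q) >= -1e-15))
    expect_true(all(enr$q >= enr$p - 1e-15))
    expect_true(all(enr$q >= 0 & enr$q <= 1))
  }
})

test_that("hit classification follows the significance and coherence rules", {
  # saturated case: result is the query's homolog set, one dominant term
  prot <- sprintf("p%02d", 1:40)
  ann <- annotation_map(c(prot[1:6], prot),
                        c(rep("gMod", 6), rep("gAll", 40)))
  cls <- classify_hits(prot[1:6], prot[1:6], ann, background = prot)
  expect_true(cls$hit && cls$FC_hit && cls$significant_hit &&
                cls$significant_FC_hit)
  expect_equal(cls$SPE, 1.0)
  expect_equal(cls$significant_SPE, 1.0)

  # nothing significant: all flags false
  withr::local_seed(4)
  ann2 <- annotation_map(sample(prot, 60, replace = TRUE),
                         sample(sprintf("g%d", 1:3), 60, replace = TRUE))
  cls2 <- classify_hits(prot[1:5], prot[6:10], ann2, background = prot,
                        p_threshold = 1e-6)
  expect_false(cls2$hit || cls2$FC_hit || cls2$significant_hit ||
                 cls2$significant_FC_hit)

  # significant but not coherent: under 50% annotated with the top term
  ann3 <- annotation_map(c(prot[1:4], prot),
                         c(rep("gRare", 4), rep("gAll", 40)))
  result <- c(prot[1:4], prot[11:20])       # 4/14 < 50% annotated gRare
  cls3 <- classify_hits(prot[1:4], result, ann3, background = prot)
  expect_true(cls3$hit)
  expect_false(cls3$FC_hit)
  expect_lt(cls3$SPE, 0.5)
})
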