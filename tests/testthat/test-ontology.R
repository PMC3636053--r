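test_that("annotation propagation follows is_a/part_of with set semantics", {
  # chain: A is_a B is_a C
  ont <- make_ontology(list(C = character(0), B = "C", A = "B"),
                       tibble::tibble(protein_id = "p1", term_id = "A"))
  prop <- propagate_annotations(ont)
  expect_equal(prop$n_proteins[match(c("A", "B", "C"), prop$term_id)],
               c(1L, 1L, 1L))

  # diamond: D -> {B, C} -> A ; protein counted once per ancestor
  ont2 <- make_ontology(list(A = character(0), B = "A", C = "A", D = c("B", "C")),
                        tibble::tibble(protein_id = "p1", term_id = "D"))
  prop2 <- propagate_annotations(ont2)
  expect_equal(prop2$n_proteins[match("A", prop2$term_id)], 1L)

  # cycle -> error
  bad <- make_ontology(list(A = "B", B = "A"))
  expect_error(propagate_annotations(bad), "cycle")
})

test_that("propagation equals a brute-force transitive closure on random DAGs", {
  set.seed(19)
  for (rep in 1:10) {
    n <- 50
    ids <- sprintf("T%02d", 1:n)
    parents <- stats::setNames(vector("list", n), ids)
    for (i in 2:n)
      parents[[i]] <- ids[sample.int(i - 1, min(i - 1, sample(1:2, 1)))]
    parents[[1]] <- character(0)
    ann <- tibble::tibble(
      protein_id = sprintf("prot%02d", 1:30),
      term_id = sample(ids, 30, TRUE))
    ont <- make_ontology(parents, ann)
    prop <- propagate_annotations(ont)
    anc <- oracle_ancestors(parents)
    for (tid in ids) {
      direct_of <- function(t) unique(ann$protein_id[ann$term_id == t])
      below <- c(tid, names(anc)[vapply(anc, function(a) tid %in% a, logical(1))])
      want <- sort(unique(unlist(lapply(below, direct_of))))
      expect_equal(prop$proteins[[match(tid, prop$term_id)]], want)
    }
  }
})

test_that("informative-term rule boundaries are exact", {
  mk <- function(root_n, child_n) {
    # root with one child; child_n annotated proteins on the child,
    # root_n - child_n extra directly on the root
    ann <- dplyr::bind_rows(
      tibble::tibble(protein_id = sprintf("c%03d", seq_len(child_n)),
                     term_id = "CHILD"),
      if (root_n > child_n)
        tibble::tibble(protein_id = sprintf("r%03d", seq_len(root_n - child_n)),
                       term_id = "ROOT"))
    make_ontology(list(ROOT = character(0), CHILD = "ROOT"), ann)
  }
  # count 30 with children at {30, 10}: child at exactly 30 is not "more than"
  ann3 <- dplyr::bind_rows(
    tibble::tibble(protein_id = sprintf("a%03d", 1:30), term_id = "C1"),
    tibble::tibble(protein_id = sprintf("a%03d", 1:10), term_id = "C2"))
  ont3 <- make_ontology(list(ROOT = character(0), C1 = "ROOT", C2 = "ROOT"), ann3)
  expect_true("ROOT" %in% informative_terms(ont3, min_count = 30))
  expect_true("C1" %in% informative_terms(ont3, min_count = 30))

  # count 29 -> not informative
  expect_false("ROOT" %in% informative_terms(mk(29, 10), min_count = 30))
  # count 100 with a child at 31 -> not informative
  expect_false("ROOT" %in% informative_terms(mk(100, 31), min_count = 30))
  expect_true("CHILD" %in% informative_terms(mk(100, 31), min_count = 30))
})

test_that("informative frontier never has an over-threshold informative descendant", {
  set.seed(23)
  for (rep in 1:5) {
    ont <- gen_ontology(40, 3, sprintf("prot%03d", 1:200), n_informative = 3,
                        seed = rep)
    info <- informative_terms(ont, min_count = 30)
    expect_gte(length(info), 3)
    prop <- propagate_annotations(ont)
    counts <- stats::setNames(prop$n_proteins, prop$term_id)
    anc <- oracle_ancestors(stats::setNames(ont$terms$parents, ont$terms$term_id))
    for (t1 in info) for (t2 in info) {
      if (t1 == t2) next
      if (t1 %in% anc[[t2]])   # t2 is a descendant of t1
        expect_lte(counts[[t2]], 30)
    }
  }
})

test_that("hypergeometric enrichment matches closed-form combinatorics", {
  # N=10, K=5, n=4, k=4 -> C(5,4) C(5,0) / C(10,4) = 5/210
  expect_equal(hypergeom_enrichment(4, 5, 4, 10)$p, 5 / 210)
  # k=0 -> upper tail includes everything
  expect_equal(hypergeom_enrichment(0, 5, 4, 10)$p, 1)
  # K=0 -> p = 1
  expect_equal(hypergeom_enrichment(0, 0, 4, 10)$p, 1)
  # k = n = K << N: p = C(K,n)/C(N,n)
  expect_equal(hypergeom_enrichment(3, 3, 3, 50)$p,
               1 / choose(50, 3) * choose(3, 3) * choose(47, 0))
  # Bonferroni multiplier caps at 1
  expect_equal(hypergeom_enrichment(1, 5, 4, 10, n_tests = 50)$p_bonferroni, 1)
})

test_that("term_enrichment tests features against informative terms", {
  ann <- dplyr::bind_rows(
    tibble::tibble(protein_id = sprintf("x%03d", 1:35), term_id = "LEAF"),
    tibble::tibble(protein_id = sprintf("y%03d", 1:32), term_id = "OTHER"))
  ont <- make_ontology(list(ROOT = character(0), LEAF = "ROOT", OTHER = "ROOT"),
                       ann)
  feats <- make_features(list(F1 = sprintf("x%03d", 1:6),
                              F2 = c(sprintf("y%03d", 1:3), "x001")))
  res <- term_enrichment(feats, ont, alpha = 0.05)
  expect_true(all(res$term_id %in% informative_terms(ont)))
  expect_true(res$significant[res$feature_id == "F1" & res$term_id == "LEAF"])
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$p_bonferroni >= res$p))
})

test_that("FCS association hit rates and boundary p-values are exact", {
  universe <- sprintf("u%02d", 1:20)
  ann <- tibble::tibble(protein_id = universe[1:8], term_id = "LIPID")
  ont <- make_ontology(list(ROOT = character(0), LIPID = "ROOT"), ann)
  # every member annotated -> rate 1, nothing can exceed it -> p = 0
  f_all <- make_features(list(F1 = universe[1:4]))
  res <- fcs_association(f_all, "LIPID", ont, universe = universe,
                         n_rand = 500, seed = 1)
  expect_equal(res$hit_rate, 1)
  expect_equal(res$p_fcs, 0)
  expect_equal(res$a, 4L)

  # no member annotated -> p approximates 1 - P(X = 0) under the hypergeometric
  f_none <- make_features(list(F0 = universe[13:16]))
  res0 <- fcs_association(f_none, "LIPID", ont, universe = universe,
                          n_rand = 4000, seed = 2)
  p_exact <- 1 - stats::dhyper(0, 8, 12, 4)
  expect_lt(abs(res0$p_fcs - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 4000))
})

test_that("FCS p converges to the exact enumeration on a toy universe", {
  # universe of 6, 3 annotated, feature of 2 with a = 1:
  # only a random pair with both proteins annotated beats rate 1/2,
  # P = C(3,2)/C(6,2) = 0.2
  universe <- sprintf("t%d", 1:6)
  ann <- tibble::tibble(protein_id = universe[1:3], term_id = "LIPID")
  ont <- make_ontology(list(LIPID = character(0)), ann)
  feat <- make_features(list(F1 = c("t1", "t4")))
  res <- fcs_association(feat, "LIPID", ont, universe = universe,
                         n_rand = 10000, seed = 3)
  expect_equal(res$hit_rate, 0.5)
  expect_lt(abs(res$p_fcs - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
})

test_that("listed-term descendants count as hits when closure is on", {
  ont <- make_ontology(list(LIPID = character(0), SUB = "LIPID"),
                       tibble::tibble(protein_id = "p1", term_id = "SUB"))
  feat <- make_features(list(F1 = c("p1", "p2")))
  with_cl <- fcs_association(feat, "LIPID", ont, universe = c("p1", "p2"),
                             n_rand = 10, seed = 1, descendants = TRUE)
  without <- fcs_association(feat, "LIPID", ont, universe = c("p1", "p2"),
                             n_rand = 10, seed = 1, descendants = FALSE)
  expect_equal(with_cl$a, 1L)
  # annotation to SUB propagates to LIPID itself, so a = 1 either way here;
  # the closure matters when the listed term has no direct/propagated link
  ont2 <- make_ontology(list(TOP = character(0), LIPID = "TOP", SUB = "LIPID"),
                        tibble::tibble(protein_id = "p1", term_id = "SUB"))
  a_closed <- fcs_association(feat, "SUB", ont2, universe = c("p1", "p2"),
                              n_rand = 10, seed = 1)$a
  expect_equal(a_closed, 1L)
})

test_that("venn bookkeeping: disjoint regions sum to the union", {
  sets <- list(BP = c("a", "b", "c", "d"), CC = c("c", "d", "e"),
               MF = c("d", "e", "f"))
  vc <- venn_counts(sets)
  expect_equal(sum(vc$count), length(unique(unlist(sets))))
  expect_lte(nrow(vc), 7)
  expect_equal(vc$count[vc$region == "BP&CC&MF"], 1L)  # just "d"
})
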