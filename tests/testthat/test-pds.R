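test_that("candidate rule: at least half of either class, ceiling on odd sizes", {
  # X in 3/5 of class A (threshold ceil(5/2)=3) and 0/7 of B -> included
  det <- c(lapply(1:3, function(i) c("X", "Y")), lapply(4:5, function(i) "Y"),
           lapply(1:7, function(i) "Z"))
  names(det) <- sprintf("p%02d", 1:12)
  cls <- stats::setNames(rep(c("A", "B"), c(5, 7)), names(det))
  prof <- make_profiles(det, cls)
  cand <- candidate_proteins(prof)
  expect_true("X" %in% cand)
  expect_true("Y" %in% cand)   # 5/5 of A
  expect_true("Z" %in% cand)   # 7/7 of B

  # W in 2/5 of A and 3/7 of B -> excluded (needs >=3 of A or >=4 of B)
  det2 <- det
  det2[["p01"]] <- c(det2[["p01"]], "W"); det2[["p02"]] <- c(det2[["p02"]], "W")
  det2[["p06"]] <- c(det2[["p06"]], "W"); det2[["p07"]] <- c(det2[["p07"]], "W")
  det2[["p08"]] <- c(det2[["p08"]], "W")
  expect_false("W" %in% candidate_proteins(make_profiles(det2, cls)))

  # one patient per class: threshold ceil(1/2) = 1, everything detected counts
  tiny <- make_profiles(list(a = "Q", b = "R"), c(a = "A", b = "B"))
  expect_setequal(candidate_proteins(tiny), c("Q", "R"))
})

test_that("PDS extraction fragments pathways and applies the size-4 floor", {
  # path A-B-C-D-E, candidates {A,B,C,D} -> one PDS of size 4
  pw <- make_pathway("P1", cbind(c("A", "B", "C", "D"), c("B", "C", "D", "E")))
  pds <- extract_pds(pw, c("A", "B", "C", "D"))
  expect_equal(nrow(pds), 1)
  expect_equal(pds$members[[1]], c("A", "B", "C", "D"))
  expect_equal(pds$source_pathway, "P1")
  expect_equal(pds$kind, "pds")

  # two components of sizes 4 and 3 -> only the 4 survives
  pw2 <- make_pathway("P2", cbind(c("A", "B", "C", "X", "Y"),
                                  c("B", "C", "D", "Y", "Z")))
  pds2 <- extract_pds(pw2, c("A", "B", "C", "D", "X", "Y", "Z"))
  expect_equal(nrow(pds2), 1)
  expect_equal(pds2$members[[1]], c("A", "B", "C", "D"))

  # no candidate overlap -> empty result
  expect_equal(nrow(extract_pds(pw, c("Q", "R"))), 0)

  # star K1,5 with all candidates -> one PDS of size 6
  star <- make_pathway("P3", cbind(rep("H", 5), paste0("L", 1:5)))
  pds3 <- extract_pds(star, c("H", paste0("L", 1:5)))
  expect_equal(pds3$n_members, 6L)
})

test_that("catalogue counts per-pathway contributions and rejects duplicates", {
  pw <- dplyr::bind_rows(
    make_pathway("P1", cbind(c("A", "B", "C"), c("B", "C", "D"))),
    make_pathway("P2", cbind(c("E", "F", "G"), c("F", "G", "H"))))
  cat_out <- pds_catalogue(pw, LETTERS[1:8])
  expect_equal(nrow(cat_out$features), 2)
  expect_equal(cat_out$contributions$n_pds, c(1L, 1L))

  dup <- dplyr::bind_rows(make_pathway("P1", cbind("A", "B")),
                          make_pathway("P1", cbind("C", "D")))
  expect_error(pds_catalogue(dup, LETTERS), "duplicate")
})

test_that("component extraction agrees with a flood-fill oracle on random graphs", {
  set.seed(41)
  for (rep in 1:100) {
    n <- sample(5:14, 1)
    nodes <- sprintf("N%02d", seq_len(n))
    n_edge <- sample(0:(2 * n), 1)
    edges <- if (n_edge > 0) {
      e <- cbind(sample(nodes, n_edge, TRUE), sample(nodes, n_edge, TRUE))
      e <- e[e[, 1] != e[, 2], , drop = FALSE]
      unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    } else matrix(character(0), 0, 2)
    cand <- sample(nodes, sample.int(n, 1))
    pw <- tibble::tibble(pathway_id = "R", name = "R",
                         nodes = list(nodes), edges = list(edges))
    got <- extract_pds(pw, cand, min_size = 1)
    keep <- intersect(nodes, cand)
    kept_edges <- edges[edges[, 1] %in% keep & edges[, 2] %in% keep, , drop = FALSE]
    want <- oracle_components(sort(keep), kept_edges)
    expect_setequal(
      vapply(got$members, paste, character(1), collapse = ","),
      vapply(want, paste, character(1), collapse = ","))
  }
})

test_that("PDS invariants: disjointness, candidate coverage, monotonicity", {
  set.seed(42)
  pw <- gen_pathways(5, sizes = 10:20, extra_edge_prob = 0.15, seed = 99)
  all_nodes <- unique(unlist(pw$nodes))
  cand_small <- sample(all_nodes, round(length(all_nodes) * 0.4))
  cand_big <- union(cand_small, sample(all_nodes, round(length(all_nodes) * 0.3)))

  pds <- extract_pds(pw, cand_small, min_size = 1)
  for (pid in unique(pds$source_pathway)) {
    mem <- pds$members[pds$source_pathway == pid]
    expect_equal(anyDuplicated(unlist(mem)), 0)           # pairwise disjoint
    nodes <- pw$nodes[[match(pid, pw$pathway_id)]]
    expect_setequal(unlist(mem), intersect(nodes, cand_small))  # full coverage
  }
  expect_true(all(unlist(pds$members) %in% cand_small))

  # enlarging candidates never splits a component: each old component stays
  # inside a single new component
  pds_big <- extract_pds(pw, cand_big, min_size = 1)
  for (i in seq_len(nrow(pds))) {
    container <- vapply(
      pds_big$members[pds_big$source_pathway == pds$source_pathway[i]],
      function(m) all(pds$members[[i]] %in% m), logical(1))
    expect_equal(sum(container), 1)
  }
})

test_that("feature IDs order components by size then smallest member", {
  edges <- cbind(c("A", "B", "C", "D", "Q", "R"),
                 c("B", "C", "D", "E", "R", "S"))  # sizes 5 and 3
  pw <- make_pathway("P9", edges)
  pds <- extract_pds(pw, c("A", "B", "C", "D", "E", "Q", "R", "S"), min_size = 3)
  expect_equal(pds$feature_id, c("P9_1", "P9_2"))
  expect_equal(pds$n_members, c(5L, 3L))
})
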