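# build a fn_contact_areas object directly from a pair list
fake_areas <- function(res_keys, pairs) {
  res <- tibble::tibble(
    res_key = res_keys,
    res_label = res_keys, chain = "A",
    resno = seq_along(res_keys), insert = "",
    resid = "LEU", n_atoms = 8L
  )
  structure(
    list(
      pairs = tibble::tibble(
        res_i = purrr::map_chr(pairs, 1),
        res_j = purrr::map_chr(pairs, 2),
        area_ij = purrr::map_dbl(pairs, 3) / 2,
        area_ji = purrr::map_dbl(pairs, 3) / 2,
        area = purrr::map_dbl(pairs, 3)
      ),
      residues = res, params = contact_params(), source_id = "fake"
    ),
    class = "fn_contact_areas"
  )
}

test_that("the 10 A^2 threshold is inclusive and singletons are dropped", {
  below <- fake_areas(c("a", "b"), list(list("a", "b", 9.9)))
  expect_equal(nrow(build_clusters(below)$clusters), 0)
  at <- fake_areas(c("a", "b"), list(list("a", "b", 10.0)))
  expect_equal(nrow(build_clusters(at)$clusters), 1)
})

test_that("clusters are the connected components of the thresholded graph", {
  ca <- fake_areas(
    letters[1:6],
    list(list("a", "b", 15), list("b", "c", 11), list("d", "e", 12),
         list("e", "f", 5))
  )
  cs <- build_clusters(ca)
  expect_equal(nrow(cs$clusters), 2)
  expect_equal(sort(cs$clusters$members[[1]]), c("a", "b", "c"))
  expect_equal(sort(cs$clusters$members[[2]]), c("d", "e"))
  # ordering: by total area descending
  expect_equal(cs$clusters$total_area, c(26, 12))
  # sub-threshold edge (e,f) contributes nothing
  expect_false("f" %in% unlist(cs$clusters$members))
})

test_that("cluster summaries report both area statistics", {
  ca <- fake_areas(c("a", "b"), list(list("a", "b", 12)))
  sm <- cluster_summary(build_clusters(ca))
  expect_equal(sm$total_area, 12)
  expect_equal(sm$n_contacts, 1L)
  expect_equal(sm$area_per_contact, 12)
  expect_equal(sm$area_per_residue, 6)

  tri <- fake_areas(c("a", "b", "c"),
                    list(list("a", "b", 10), list("b", "c", 10),
                         list("a", "c", 10)))
  sm2 <- cluster_summary(build_clusters(tri))
  expect_equal(sm2$total_area, 30)
  expect_equal(sm2$n_contacts, 3L)
  expect_equal(sm2$area_per_contact, 10)
})

test_that("components agree with an independent graph oracle", {
  skip_if_not_installed("igraph")
  set.seed(11)
  n <- 100
  keys <- sprintf("r%03d", seq_len(n))
  for (trial in seq_len(500)) {
    n_edges <- sample(0:60, 1)
    eij <- matrix(sample(n, 2 * n_edges, replace = TRUE), ncol = 2)
    eij <- eij[eij[, 1] != eij[, 2], , drop = FALSE]
    pairs <- purrr::map(seq_len(nrow(eij)), function(k) {
      list(keys[eij[k, 1]], keys[eij[k, 2]], 10 + stats::runif(1, 0, 5))
    })
    if (length(pairs) == 0) next
    cs <- build_clusters(fake_areas(keys, pairs))
    # oracle membership restricted to clustered residues
    mem <- igraph_components(keys, keys[eij[, 1]], keys[eij[, 2]])
    for (k in seq_len(nrow(cs$clusters))) {
      grp <- cs$clusters$member_keys[[k]]
      expect_length(unique(mem[grp]), 1)
      # maximality: no other residue shares the oracle component
      comp_id <- mem[grp[1]]
      expect_setequal(grp, names(mem)[mem == comp_id])
    }
  }
})

test_that("raising the threshold only removes or splits clusters", {
  s <- place_residues(
    c("LEU", "ILE", "VAL", "LEU"),
    list(c(0, 0, 0), c(6.5, 1, 0), c(3, 4.8, 0.5), c(13, 1.5, 0)),
    rotations = c(0, 180, 90, 180)
  )
  ca <- contact_areas(s)
  thresholds <- c(1, 5, 10, 20, 40)
  sets <- purrr::map(thresholds, function(th) {
    build_clusters(ca, cluster_params(area_threshold = th))
  })
  n_res <- purrr::map_int(sets, ~ sum(.x$clusters$size))
  expect_true(all(diff(n_res) <= 0)) # clustered residues never increase
  for (k in seq_along(sets)[-1]) {
    # every cluster at the higher threshold is inside one earlier cluster
    for (grp in sets[[k]]$clusters$member_keys) {
      containing <- purrr::map_lgl(sets[[k - 1]]$clusters$member_keys,
                                   ~ all(grp %in% .x))
      expect_equal(sum(containing), 1)
    }
  }
})

test_that("hydrophobic_clusters runs end-to-end on a packed ILV triad", {
  s <- make_mini_protein()
  cs <- hydrophobic_clusters(s)
  expect_gte(nrow(cs$clusters), 1)
  expect_true(all(unlist(cs$clusters$members) %in%
                    c("LEU1", "ILE2", "VAL3")))
  expect_true(all(cs$contacts$area >= 10))
  g <- glance(cs)
  expect_equal(g$n_clusters, nrow(cs$clusters))
  # sum of cluster sizes cannot exceed the ILV residue count
  expect_lte(sum(cs$clusters$size), 3)
})
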