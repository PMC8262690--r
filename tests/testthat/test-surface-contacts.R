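# helper: two lone "carbon residues" at distance D along x
carbon_pair <- function(D) {
  as_structure(tibble::tibble(
    name = c("C1", "C1"), resid = "UNK", resno = c(1L, 2L),
    x = c(0, D), y = 0, z = 0, element = "C"
  ))
}

test_that("the Fibonacci grid is unit-norm with equal-area sections", {
  g <- fibonacci_grid(610)
  expect_equal(g$n, 610L)
  norms <- sqrt(rowSums(g$directions^2))
  expect_true(all(abs(norms - 1) < 1e-12))
  expect_equal(g$fraction, 1 / 610)
  expect_equal(round(g$fraction, 4), 0.0016)
  # near-uniform lattices are balanced
  com <- colMeans(fibonacci_grid(200)$directions)
  expect_lt(sqrt(sum(com^2)), 0.05)
  expect_error(fibonacci_grid(5), ">= 12")
})

test_that("candidate neighbours respect the extended-radius cutoff", {
  s1 <- carbon_pair(6.50)
  expect_equal(nrow(neighbor_candidates(s1, serial = 1)), 1)
  s2 <- carbon_pair(6.60)
  expect_equal(nrow(neighbor_candidates(s2, serial = 1)), 0)
  # an atom is never its own candidate, nor are same-residue atoms
  s3 <- as_structure(tibble::tibble(
    name = c("C1", "C2"), resid = "UNK", resno = 1L,
    x = c(0, 1.5), y = 0, z = 0, element = "C"
  ))
  expect_equal(nrow(neighbor_candidates(s3, serial = 1)), 0)
})

test_that("section ownership follows the closest-centre rule", {
  s <- carbon_pair(30)
  nb <- neighbor_candidates(s, 1)
  expect_equal(nrow(nb), 0)
  own_none <- assign_sections(s, 1, nb)
  expect_true(all(is.na(own_none)))

  # an engulfing neighbour owns every section
  s_eng <- as_structure(tibble::tibble(
    name = c("C1", "X1"), resid = "UNK", resno = c(1L, 2L),
    x = c(0, 0.1), y = 0, z = 0, element = c("C", "XBIG")
  ))
  rt <- radius_table(default = 12) # extended radius swallows the shell
  suppressWarnings({
    nb <- neighbor_candidates(s_eng, 1, radii = rt)
    own <- assign_sections(s_eng, 1, nb, radii = rt)
  })
  expect_true(all(own == 2L))

  # contested sections go to the closer neighbour
  s3 <- as_structure(tibble::tibble(
    name = c("C1", "C1", "C1"), resid = "UNK", resno = 1:3,
    x = c(0, 3, 4), y = 0, z = 0, element = "C"
  ))
  nb <- neighbor_candidates(s3, 1)
  own <- assign_sections(s3, 1, nb)
  owned <- own[!is.na(own)]
  # every section claimable by atom 3 is also inside atom 2's sphere on
  # the +x side; where both claim, serial 2 (closer, 3 A) must win
  expect_true(any(owned == 2L))
  p <- sweep(fibonacci_grid(610)$directions * 3.28, 2, c(0, 0, 0), "+")
  both <- (p[, 1] - 3)^2 + p[, 2]^2 + p[, 3]^2 <= 3.28^2 &
    (p[, 1] - 4)^2 + p[, 2]^2 + p[, 3]^2 <= 3.28^2
  expect_true(all(own[both] == 2L))
})

test_that("directed areas match a dense Monte-Carlo oracle within 3%", {
  set.seed(7)
  ndir <- 1e5
  u <- matrix(stats::rnorm(3 * ndir), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  for (D in seq(3, 6, by = 0.5)) {
    s <- carbon_pair(D)
    ca <- contact_areas(s)
    area <- if (nrow(ca$pairs) > 0) ca$pairs$area_ij[1] else 0
    rext <- 1.88 + 1.4
    inside <- (u[, 1] * rext - D)^2 + (u[, 2] * rext)^2 +
      (u[, 3] * rext)^2 <= rext^2
    mc <- mean(inside) * 4 * pi * rext^2
    expect_equal(area, mc, tolerance = 0.03)
  }
})

test_that("grid areas converge and tiny near-cutoff caps stay within one section", {
  # at 6.5 A the overlap cap is smaller than a few sections; the grid
  # can only resolve it to quantisation accuracy
  s <- carbon_pair(6.5)
  rext <- 3.28
  cap <- function(D) 2 * pi * rext^2 * (1 - (D^2) / (2 * D * rext))
  a610 <- contact_areas(s)$pairs$area_ij[1]
  sec <- 4 * pi * rext^2 / 610
  expect_lt(abs(a610 - cap(6.5)), sec)
})

test_that("per-atom section areas are conserved exactly", {
  s <- carbon_pair(4)
  nb <- neighbor_candidates(s, 1)
  own <- assign_sections(s, 1, nb)
  g <- fibonacci_grid(610)
  rext <- 3.28
  total <- 4 * pi * rext^2
  owned_area <- sum(!is.na(own)) * total * g$fraction
  unowned_area <- sum(is.na(own)) * total * g$fraction
  expect_identical(length(own), 610L)
  expect_equal(owned_area + unowned_area, total, tolerance = 1e-12)
})

test_that("directed areas between identical atoms agree to grid resolution", {
  s <- carbon_pair(4)
  ca <- contact_areas(s)
  # the two directions use the same fixed lattice seen from opposite
  # sides, so they agree only to section quantisation
  sec <- 4 * pi * 3.28^2 / 610
  expect_lt(abs(ca$pairs$area_ij - ca$pairs$area_ji), 5 * sec)
  expect_equal(ca$pairs$area, ca$pairs$area_ij + ca$pairs$area_ji)
  # swapping the atom order leaves the symmetrised area unchanged
  s_swap <- as_structure(tibble::tibble(
    name = c("C1", "C1"), resid = "UNK", resno = c(1L, 2L),
    x = c(4, 0), y = 0, z = 0, element = "C"
  ))
  expect_equal(contact_areas(s_swap)$pairs$area, ca$pairs$area)
})

test_that("enlarging a neighbour's radius never shrinks its directed area", {
  areas <- purrr::map_dbl(c(1.6, 1.8, 2.0, 2.2), function(rb) {
    s <- as_structure(tibble::tibble(
      name = c("C1", "Q1"), resid = "UNK", resno = c(1L, 2L),
      x = c(0, 4.5), y = 0, z = 0, element = c("C", "Q")
    ))
    suppressWarnings(
      ca <- contact_areas(s, radii = radius_table(default = rb))
    )
    if (nrow(ca$pairs) > 0) ca$pairs$area_ij[1] else 0
  })
  expect_true(all(diff(areas) >= 0))
})

test_that("grid refinement changes fixture areas by under 5%", {
  s <- read_structure(text = make_pair("LEU", "ILE", 4))
  a1 <- contact_areas(s, params = contact_params(n_sections = 610))
  a2 <- contact_areas(s, params = contact_params(n_sections = 6100))
  expect_equal(a1$pairs$area, a2$pairs$area, tolerance = 0.05)
})

test_that("contact areas are exactly translation-invariant", {
  s <- read_structure(text = make_pair("LEU", "ILE", 4))
  ca1 <- contact_areas(s)
  ca2 <- contact_areas(rigid_transform(s, angle = 0, shift = c(8, -2, 5)))
  expect_equal(ca1$pairs$area, ca2$pairs$area, tolerance = 1e-12)
  expect_equal(ca1$pairs$res_i, ca2$pairs$res_i)
})

test_that("rotation changes areas only at section-quantisation level", {
  s <- read_structure(text = make_pair("LEU", "ILE", 4))
  ca1 <- contact_areas(s)
  ca2 <- contact_areas(rigid_transform(s, angle = 37))
  expect_equal(ca1$pairs$area, ca2$pairs$area, tolerance = 0.02)
})

test_that("residues beyond candidacy have zero contact area", {
  s <- read_structure(text = make_pair("LEU", "LEU", 20))
  ca <- contact_areas(s)
  expect_equal(nrow(ca$pairs), 0)
  expect_true(all(area_matrix(ca) == 0))
})

test_that("selection handling: errors and occluder scope", {
  s <- read_structure(text = make_pair("LEU", "ILE", 4))
  expect_error(contact_areas(s, character(0)), "empty")
  expect_error(contact_areas(s, "A|9||GLY"), "not in structure")
  # occluders outside the selection never appear as cells
  tri <- place_residues(c("LEU", "ILE", "SER"),
                        list(c(0, 0, 0), c(7, 1, 0), c(3.5, 4, 0)),
                        rotations = c(0, 180, 90))
  res <- residue_table(tri)
  sel <- res$res_key[res$resid != "SER"]
  ca <- contact_areas(tri, sel)
  expect_true(all(ca$pairs$res_i %in% sel))
  expect_true(all(ca$pairs$res_j %in% sel))
})
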