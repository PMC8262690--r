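# minimal structure with an explicit donor-H-acceptor triple
triple_structure <- function(d = 2.0, theta = 180, donor_el = "O") {
  # donor at origin, H along +x, acceptor in the xz-plane at angle theta
  h <- c(0.96, 0, 0)
  dir <- c(cos(foldnets:::deg2rad(180 - theta)),
           0, sin(foldnets:::deg2rad(180 - theta)))
  acc <- h + d * dir
  as_structure(tibble::tibble(
    name = c("OG", "HG", "OD1"),
    element = c(donor_el, "H", "O"),
    resid = c("SER", "SER", "ASP"),
    resno = c(1L, 1L, 2L),
    x = c(0, h[1], acc[1]), y = c(0, h[2], acc[2]), z = c(0, h[3], acc[3])
  ))
}

test_that("the angle and distance cutoffs are strict", {
  expect_equal(nrow(detect_hbonds(triple_structure(2.0, 180))), 1)
  expect_equal(nrow(detect_hbonds(triple_structure(2.0, 110))), 0)
  expect_equal(nrow(detect_hbonds(triple_structure(2.6, 180))), 0)
  b <- detect_hbonds(triple_structure(2.0, 150))
  expect_equal(b$d, 2.0, tolerance = 1e-9)
  expect_equal(b$theta, 150, tolerance = 1e-9)
  # every reported bond satisfies its own cutoffs
  expect_true(all(b$d < 2.5 & b$theta > 120))
})

test_that("unprotonated structures are rejected with guidance", {
  s <- read_structure(text = make_pair("SER", "ASP", 2.8))
  expect_error(detect_hbonds(s), "protonate")
})

test_that("protonation places fixed pH-7 hydrogens with ideal geometry", {
  ser <- protonate(as_structure(residue_template("SER")))
  h <- ser[ser$element == "H", ]
  expect_equal(nrow(h), 1)
  og <- ser[ser$name == "OG", ]
  expect_equal(sqrt((h$x - og$x)^2 + (h$y - og$y)^2 + (h$z - og$z)^2),
               0.96, tolerance = 0.01)

  asp <- protonate(as_structure(residue_template("ASP")))
  expect_equal(sum(asp$element == "H"), 0) # carboxylate stays bare

  lys <- protonate(as_structure(residue_template("LYS")))
  hz <- lys[grepl("^HZ", lys$name), ]
  expect_equal(nrow(hz), 3)
  nz <- unlist(lys[lys$name == "NZ", c("x", "y", "z")])
  hpos <- lapply(seq_len(3), function(i) unlist(hz[i, c("x", "y", "z")]))
  for (i in 1:2) for (j in (i + 1):3) {
    ang <- foldnets:::angle_deg(hpos[[i]], nz, hpos[[j]])
    expect_equal(ang, 109.5, tolerance = 5)
  }

  arg <- protonate(as_structure(residue_template("ARG")))
  expect_equal(sum(arg$element == "H"), 5) # guanidinium
  gln <- protonate(as_structure(residue_template("GLN")))
  expect_equal(sum(gln$element == "H"), 2)
  his <- protonate(as_structure(residue_template("HIS")))
  expect_equal(sum(his$element == "H"), 1) # single neutral tautomer
  expect_true(his$name[his$element == "H"] %in% c("HD1", "HE2"))
})

test_that("existing hydrogens are kept, not duplicated", {
  ser <- protonate(as_structure(residue_template("SER")))
  again <- protonate(ser)
  expect_equal(sum(again$element == "H"), 1)
  expect_equal(again$x, ser$x)
})

test_that("a serine-aspartate pair forms one hydrogen bond after protonation", {
  s <- read_structure(text = make_pair("SER", "ASP", 2.8,
                                       approach_angle = -70))
  b <- detect_hbonds(protonate(s))
  expect_equal(nrow(b), 1)
  expect_equal(b$donor_atom, "OG")
  expect_true(b$acceptor_atom %in% c("OD1", "OD2"))
  expect_lt(b$d, 2.5)
  expect_gt(b$theta, 120)
})

test_that("sidechain-only scope excludes backbone partners", {
  s <- triple_structure(2.0, 180)
  atoms <- tibble::as_tibble(s)
  atoms$name[atoms$name == "OD1"] <- "O" # backbone carbonyl name
  s_bb <- as_structure(atoms)
  expect_equal(nrow(detect_hbonds(s_bb)), 0)
  expect_equal(nrow(detect_hbonds(s_bb, hbond_params(scope = "all"))), 1)
})

test_that("widening the cutoffs never removes a bond", {
  s <- protonate(read_structure(text = make_pair("SER", "ASP", 2.8,
                                                 approach_angle = -70)))
  strict <- detect_hbonds(s, hbond_params(theta_min = 150, d_max = 2.0))
  loose <- detect_hbonds(s, hbond_params(theta_min = 120, d_max = 2.5))
  key <- function(b) paste(b$h_atom, b$acceptor_res, b$acceptor_atom)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("bond detection is invariant under rigid transforms", {
  s <- protonate(read_structure(text = make_pair("SER", "ASP", 2.8,
                                                 approach_angle = -70)))
  b1 <- detect_hbonds(s)
  b2 <- detect_hbonds(rigid_transform(s))
  expect_equal(nrow(b1), nrow(b2))
  expect_equal(b1$d, b2$d, tolerance = 1e-9)
  expect_equal(b1$theta, b2$theta, tolerance = 1e-9)
})

test_that("networks are path-connected components of the bond graph", {
  bonds <- foldnets:::empty_hbond_tbl()
  add_bond <- function(b, dres, ares) {
    dplyr::bind_rows(b, tibble::tibble(
      donor_res = paste0("A|", dres, "||XXX"), donor_label = paste0("X", dres),
      donor_atom = "OG", h_atom = "HG",
      acceptor_res = paste0("A|", ares, "||XXX"),
      acceptor_label = paste0("X", ares),
      acceptor_atom = "OD1", d = 2.0, theta = 160
    ))
  }
  bonds <- add_bond(add_bond(bonds, 1, 2), 2, 3)
  nw <- build_networks(bonds)
  expect_equal(nrow(nw$networks), 1)
  expect_equal(nw$networks$size, 3)
  expect_equal(nw$bonds$network, c(1L, 1L))

  empty <- build_networks(foldnets:::empty_hbond_tbl())
  expect_equal(nrow(empty$networks), 0)
})

test_that("network partitions match the independent components oracle", {
  skip_if_not_installed("igraph")
  set.seed(23)
  for (trial in 1:50) {
    n_bonds <- sample(1:25, 1)
    res_ids <- sample(1:30, 2 * n_bonds, replace = TRUE)
    di <- res_ids[seq_len(n_bonds)]
    ai <- res_ids[n_bonds + seq_len(n_bonds)]
    keep <- di != ai
    if (!any(keep)) next
    bonds <- tibble::tibble(
      donor_res = paste0("A|", di[keep], "||XXX"),
      donor_label = paste0("X", di[keep]),
      donor_atom = "OG", h_atom = "HG",
      acceptor_res = paste0("A|", ai[keep], "||XXX"),
      acceptor_label = paste0("X", ai[keep]),
      acceptor_atom = "OD1", d = 2.0, theta = 160
    )
    nw <- build_networks(bonds)
    mem <- igraph_components(unique(c(bonds$donor_res, bonds$acceptor_res)),
                             bonds$donor_res, bonds$acceptor_res)
    for (k in seq_len(nrow(nw$networks))) {
      grp <- nw$networks$member_keys[[k]]
      expect_length(unique(mem[grp]), 1)
      expect_setequal(grp, names(mem)[mem == mem[grp[1]]])
    }
    # partition covers every bonded residue exactly once
    expect_setequal(unlist(nw$networks$member_keys), names(mem))
  }
})
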