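# Shared helpers: composite synthetic structures and independent oracles.

# Place idealised residues at given xyz offsets (list of 3-vectors),
# optionally rotating each about z; returns a structure tibble.
place_residues <- function(types, offsets, rotations = NULL) {
  stopifnot(length(types) == length(offsets))
  atoms <- purrr::imap(types, function(tp, i) {
    r <- foldnets::residue_template(tp, resno = i)
    xyz <- as.matrix(r[, c("x", "y", "z")])
    if (!is.null(rotations) && rotations[i] != 0) {
      xyz <- xyz %*% t(foldnets:::rotation_matrix(c(0, 0, 1), rotations[i]))
    }
    xyz <- sweep(xyz, 2, offsets[[i]], "+")
    r$x <- xyz[, 1]; r$y <- xyz[, 2]; r$z <- xyz[, 3]
    r
  })
  foldnets::as_structure(dplyr::bind_rows(atoms))
}

# A compact synthetic "mini-protein": three mutually packed ILV residues,
# a Lys-Glu salt-bridge pair and a Ser-Asp hydrogen-bond pair, all far
# enough apart not to interact across groups.
make_mini_protein <- function() {
  ilv <- place_residues(
    c("LEU", "ILE", "VAL"),
    list(c(0, 0, 0), c(10.5, 1.5, 0), c(4.5, 6.5, 1.0)),
    rotations = c(0, 180, 90)
  )
  salt <- read_structure(text = make_pair("LYS", "GLU", 3.5))
  hb <- read_structure(text = make_pair("SER", "ASP", 2.8,
                                        approach_angle = -70))
  shift_res <- function(s, dx, dy, start_no) {
    a <- tibble::as_tibble(s)
    a$x <- a$x + dx; a$y <- a$y + dy
    a$resno <- a$resno + start_no - 1L
    a[, c("name", "element", "resid", "resno", "x", "y", "z")]
  }
  foldnets::as_structure(dplyr::bind_rows(
    shift_res(ilv, 0, 0, 1L),
    shift_res(salt, 40, 0, 4L),
    shift_res(hb, 0, 40, 6L)
  ), source_id = "mini-protein")
}

# rigid transform of a structure (fixed rotation + translation)
rigid_transform <- function(s, axis = c(1, 2, 3), angle = 37,
                            shift = c(5, -3, 11)) {
  a <- tibble::as_tibble(s)
  rot <- foldnets:::rotation_matrix(axis, angle)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rot)
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  foldnets::as_structure(a, source_id = attr(s, "source_id"))
}

# independent connected-components oracle (igraph)
igraph_components <- function(nodes, edges_i, edges_j) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges_i, to = edges_j),
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  igraph::components(g)$membership[nodes]
}

# direct-summation delta oracle, written independently of delta_rows
delta_oracle <- function(charges, g) {
  L <- length(charges)
  fp <- mean(charges == 1)
  fm <- mean(charges == -1)
  sigma <- if (fp + fm > 0) (fp - fm)^2 / (fp + fm) else 0
  devs <- numeric(L - g + 1)
  for (w in seq_len(L - g + 1)) {
    blob <- charges[w:(w + g - 1)]
    bp <- mean(blob == 1)
    bm <- mean(blob == -1)
    s_i <- if (bp + bm > 0) (bp - bm)^2 / (bp + bm) else 0
    devs[w] <- (s_i - sigma)^2
  }
  mean(devs)
}

# brute-force delta_max oracle by explicit enumeration (independent of
# the package's enumerator: recursion over positions)
delta_max_oracle <- function(np, nm, n0, g) {
  best <- -Inf
  L <- np + nm + n0
  recurse <- function(prefix, np, nm, n0) {
    if (length(prefix) == L) {
      best <<- max(best, delta_oracle(prefix, g))
      return(invisible())
    }
    if (np > 0) recurse(c(prefix, 1L), np - 1L, nm, n0)
    if (nm > 0) recurse(c(prefix, -1L), np, nm - 1L, n0)
    if (n0 > 0) recurse(c(prefix, 0L), np, nm, n0 - 1L)
  }
  recurse(integer(0), np, nm, n0)
  best
}
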