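#' Fibonacci lattice of equal-area sections on the unit sphere
#'
#' Generates `n` near-uniform directions with the golden-angle Fibonacci
#' lattice. Each direction represents a section of the sphere carrying an
#' equal share `1/n` of its area; with the default `n = 610` each section
#' is 0.0016 of the sphere.
#'
#' @param n Number of sections (at least 12; default 610).
#' @return A `fn_section_grid`: a list with `directions` (`n x 3` matrix
#'   of unit vectors), `n` and `fraction = 1/n`.
#' @export
#' @examples
#' g <- fibonacci_grid(610)
#' g$fraction * g$n
fibonacci_grid <- function(n = 610) {
  if (!is.numeric(n) || n < 12) abort("`n` must be an integer >= 12")
  n <- as.integer(n)
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  structure(list(directions = dirs, n = n, fraction = 1 / n),
            class = "fn_section_grid")
}

#' Parameters for the surface-section contact-area computation
#'
#' @param n_sections Sections per atom sphere (default 610).
#' @param probe_radius Water probe radius in Angstrom (default 1.4).
#' @param area_sphere Sphere whose area the sections measure:
#'   `"solvent-extended"` (radius r + probe, the sphere the probe
#'   centres lie on; default) or `"van-der-waals"` (bare atomic radius).
#' @param occluder_scope `"all-heavy-atoms"` (every heavy atom of the
#'   structure competes for sections; default) or `"selection-only"`.
#' @return A list of class `fn_contact_params`.
#' @export
contact_params <- function(n_sections = 610, probe_radius = 1.4,
                           area_sphere = c("solvent-extended", "van-der-waals"),
                           occluder_scope = c("all-heavy-atoms", "selection-only")) {
  if (!is.numeric(n_sections) || n_sections < 12) {
    abort("`n_sections` must be >= 12")
  }
  if (!is.numeric(probe_radius) || probe_radius <= 0) {
    abort("`probe_radius` must be > 0")
  }
  structure(
    list(
      n_sections = as.integer(n_sections), probe_radius = probe_radius,
      area_sphere = match.arg(area_sphere),
      occluder_scope = match.arg(occluder_scope)
    ),
    class = "fn_contact_params"
  )
}

# All candidate heavy-atom pairs within per-pair extended-radius cutoffs,
# found with a uniform-grid spatial index (cells of the maximum cutoff) so
# the search is subquadratic in the number of atoms.
extended_neighbor_pairs <- function(xyz, rext) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  maxcut <- 2 * max(rext)
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / maxcut)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  by_cell <- split(seq_len(n), key)
  cell_xyz <- do.call(rbind, lapply(strsplit(names(by_cell), " "), as.integer))
  key_index <- setNames(seq_along(by_cell), names(by_cell))

  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  # half-space of offsets so each cell pair is visited once
  offsets <- offsets[offsets[, 1] > 0 |
                       (offsets[, 1] == 0 & offsets[, 2] > 0) |
                       (offsets[, 1] == 0 & offsets[, 2] == 0 & offsets[, 3] >= 0), ,
                     drop = FALSE]
  out <- vector("list", length(by_cell) * nrow(offsets))
  k <- 0L
  for (ci in seq_along(by_cell)) {
    ii <- by_cell[[ci]]
    for (oi in seq_len(nrow(offsets))) {
      same <- all(offsets[oi, ] == 0)
      if (same) {
        jj <- ii
      } else {
        nb_key <- paste(cell_xyz[ci, 1] + offsets[oi, 1],
                        cell_xyz[ci, 2] + offsets[oi, 2],
                        cell_xyz[ci, 3] + offsets[oi, 3])
        cj <- key_index[nb_key]
        if (is.na(cj)) next
        jj <- by_cell[[cj]]
      }
      d2 <- outer(xyz[ii, 1], xyz[jj, 1], "-")^2 +
        outer(xyz[ii, 2], xyz[jj, 2], "-")^2 +
        outer(xyz[ii, 3], xyz[jj, 3], "-")^2
      cut2 <- outer(rext[ii], rext[jj], "+")^2
      hit <- which(d2 <= cut2, arr.ind = TRUE)
      if (same) hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      if (nrow(hit) > 0) {
        k <- k + 1L
        out[[k]] <- cbind(ii[hit[, 1]], jj[hit[, 2]])
      }
    }
  }
  if (k == 0L) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out[seq_len(k)])
}

#' Candidate contact neighbours of one atom
#'
#' Heavy atoms of other residues whose centre lies within the sum of the
#' two solvent-extended radii, `(r_A + probe) + (r_B + probe)` — for two
#' carbons, within 6.56 A.
#'
#' @param structure A structure tibble.
#' @param serial Serial number of the query atom.
#' @param params A [contact_params()].
#' @param radii A [radius_table()].
#' @return The rows of `structure` that are candidates, as a tibble.
#' @export
neighbor_candidates <- function(structure, serial, params = contact_params(),
                                radii = radius_table()) {
  atoms <- as_tibble(structure)
  i <- match(serial, atoms$serial)
  if (is.na(i)) abort("`serial` not found in structure")
  heavy <- atoms[atoms$is_heavy, , drop = FALSE]
  a <- atoms[i, ]
  r_a <- vdw_radius(a$element, radii) + params$probe_radius
  r_b <- vdw_radius(heavy$element, radii) + params$probe_radius
  d <- sqrt((heavy$x - a$x)^2 + (heavy$y - a$y)^2 + (heavy$z - a$z)^2)
  keep <- d <= (r_a + r_b) & heavy$res_key != a$res_key
  heavy[keep, , drop = FALSE]
}

# Section ownership for one atom given candidate neighbour indices.
# Probe positions P = center + (r_a + probe) * u are claimed by any
# neighbour with |P - c_B| <= r_B + probe; the owner among claimants is
# the neighbour whose centre is closest to the atom centre, ties broken
# by lower serial. Returns an integer vector over sections with the index
# (into `nb_idx`) of the owner, or NA.
section_owners <- function(center, r_ext_a, nb_xyz, nb_rext, nb_dist,
                           nb_serial, grid) {
  n_sec <- grid$n
  owner <- rep(NA_integer_, n_sec)
  if (nrow(nb_xyz) == 0) return(owner)
  p <- sweep(grid$directions * r_ext_a, 2, center, "+")
  ord <- order(nb_dist, nb_serial)
  unclaimed <- rep(TRUE, n_sec)
  for (j in ord) {
    if (!any(unclaimed)) break
    d2 <- (p[unclaimed, 1] - nb_xyz[j, 1])^2 +
      (p[unclaimed, 2] - nb_xyz[j, 2])^2 +
      (p[unclaimed, 3] - nb_xyz[j, 3])^2
    hit <- d2 <= nb_rext[j]^2
    if (any(hit)) {
      idx <- which(unclaimed)[hit]
      owner[idx] <- j
      unclaimed[idx] <- FALSE
    }
  }
  owner
}

#' Assign surface sections of one atom to occluding neighbours
#'
#' For each section direction the probe position is tested against every
#' candidate neighbour; a section claimed by several neighbours belongs
#' to the one whose centre is closest to the atom centre (ties broken by
#' lower serial).
#'
#' @inheritParams neighbor_candidates
#' @param neighbors Tibble of candidate atoms from
#'   [neighbor_candidates()].
#' @param grid A [fibonacci_grid()]; defaults to one built from `params`.
#' @return Integer vector of length `grid$n`: the owning atom's serial
#'   per section, `NA` for unowned sections.
#' @export
assign_sections <- function(structure, serial, neighbors,
                            params = contact_params(),
                            radii = radius_table(), grid = NULL) {
  if (is.null(grid)) grid <- fibonacci_grid(params$n_sections)
  atoms <- as_tibble(structure)
  a <- atoms[match(serial, atoms$serial), ]
  r_ext_a <- vdw_radius(a$element, radii) + params$probe_radius
  nb_xyz <- as.matrix(neighbors[, c("x", "y", "z")])
  nb_rext <- vdw_radius(neighbors$element, radii) + params$probe_radius
  nb_dist <- sqrt((neighbors$x - a$x)^2 + (neighbors$y - a$y)^2 +
                    (neighbors$z - a$z)^2)
  own <- section_owners(c(a$x, a$y, a$z), r_ext_a, nb_xyz, nb_rext,
                        nb_dist, neighbors$serial, grid)
  neighbors$serial[own]
}

#' Residue-residue contact areas by the surface-section algorithm
#'
#' Implements the contacts-of-structural-units construction: each heavy
#' atom's solvent-extended sphere is discretised into `n_sections`
#' equal-area sections with a Fibonacci lattice; a section overlapped by
#' one or more neighbouring atoms' solvent-extended spheres is assigned
#' to the neighbour whose centre is closest; each owned section
#' contributes its area share to the (residue of the atom, residue of the
#' owner) cell. The matrix is then symmetrised by summing the two
#' directed totals.
#'
#' @param structure A structure tibble.
#' @param selection Character vector of `res_key`s (or a logical/integer
#'   residue selector over [residue_table()] rows) whose pairwise areas
#'   are accumulated. Defaults to all residues.
#' @param params A [contact_params()].
#' @param radii A [radius_table()].
#' @return An object of class `fn_contact_areas`: list with `pairs`
#'   (tibble of residue pairs with directed and symmetrised areas in A^2),
#'   `residues` (residue table of the selection), `params`.
#' @export
contact_areas <- function(structure, selection = NULL,
                          params = contact_params(),
                          radii = radius_table()) {
  atoms <- as_tibble(structure)
  res <- residue_table(structure)
  if (is.null(selection)) selection <- res$res_key
  if (is.logical(selection) || is.numeric(selection)) {
    selection <- res$res_key[selection]
  }
  if (length(selection) == 0) abort("empty residue selection")
  bad <- setdiff(selection, res$res_key)
  if (length(bad) > 0) {
    abort(paste0("selection residues not in structure: ",
                 paste(head(bad, 5), collapse = ", ")))
  }

  heavy <- atoms[atoms$is_heavy, , drop = FALSE]
  if (params$occluder_scope == "selection-only") {
    heavy <- heavy[heavy$res_key %in% selection, , drop = FALSE]
  }
  sel_atom <- heavy$res_key %in% selection
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  rext <- vdw_radius(heavy$element, radii) + params$probe_radius
  grid <- fibonacci_grid(params$n_sections)

  pairs <- extended_neighbor_pairs(xyz, rext)
  # drop intra-residue pairs; expand to directed adjacency
  if (nrow(pairs) > 0) {
    keep <- heavy$res_key[pairs[, 1]] != heavy$res_key[pairs[, 2]]
    pairs <- pairs[keep, , drop = FALSE]
  }
  nb_of <- split(c(pairs[, 2], pairs[, 1]), c(pairs[, 1], pairs[, 2]))

  acc <- new.env(parent = emptyenv())
  for (ai in which(sel_atom)) {
    nbs <- nb_of[[as.character(ai)]]
    if (is.null(nbs)) next
    nb_dist <- sqrt((xyz[nbs, 1] - xyz[ai, 1])^2 +
                      (xyz[nbs, 2] - xyz[ai, 2])^2 +
                      (xyz[nbs, 3] - xyz[ai, 3])^2)
    own <- section_owners(xyz[ai, ], rext[ai], xyz[nbs, , drop = FALSE],
                          rext[nbs], nb_dist, heavy$serial[nbs], grid)
    owned <- own[!is.na(own)]
    if (length(owned) == 0) next
    r_area <- if (params$area_sphere == "solvent-extended") {
      rext[ai]
    } else {
      rext[ai] - params$probe_radius
    }
    sec_area <- 4 * pi * r_area^2 * grid$fraction
    counts <- table(heavy$res_key[nbs[owned]])
    # only selection-selection cells accumulate area
    counts <- counts[names(counts) %in% selection]
    for (rk in names(counts)) {
      key <- paste(heavy$res_key[ai], rk, sep = "\r")
      acc[[key]] <- (acc[[key]] %||% 0) + counts[[rk]] * sec_area
    }
  }

  keys <- ls(acc)
  if (length(keys) == 0) {
    directed <- tibble(res_i = character(0), res_j = character(0),
                       area = numeric(0))
  } else {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    directed <- tibble(
      res_i = vapply(parts, `[[`, character(1), 1),
      res_j = vapply(parts, `[[`, character(1), 2),
      area = vapply(keys, function(k) acc[[k]], numeric(1))
    )
  }

  # symmetrise: area(i,j) = directed(i->j) + directed(j->i), i < j by
  # selection order
  ord <- match(directed$res_i, selection) < match(directed$res_j, selection)
  sym <- directed |>
    mutate(
      a = ifelse(ord, .data$res_i, .data$res_j),
      b = ifelse(ord, .data$res_j, .data$res_i),
      dir = ifelse(ord, "ij", "ji")
    ) |>
    group_by(.data$a, .data$b) |>
    summarise(
      area_ij = sum(.data$area[.data$dir == "ij"]),
      area_ji = sum(.data$area[.data$dir == "ji"]),
      area = sum(.data$area), .groups = "drop"
    ) |>
    rename(res_i = "a", res_j = "b") |>
    arrange(match(.data$res_i, selection), match(.data$res_j, selection))

  res_sel <- res[match(selection, res$res_key), , drop = FALSE]
  structure(
    list(pairs = sym, residues = res_sel, params = params,
         source_id = attr(structure, "source_id")),
    class = "fn_contact_areas"
  )
}

#' @export
print.fn_contact_areas <- function(x, ...) {
  cat("Residue contact areas (", nrow(x$residues), " residues, ",
      nrow(x$pairs), " contacting pairs)\n", sep = "")
  print(x$pairs, ...)
  invisible(x)
}

#' Tidy residue contact areas into a long tibble
#' @param x A `fn_contact_areas` object.
#' @param ... Unused.
#' @return Tibble with residue labels and directed plus symmetrised areas.
#' @export
tidy.fn_contact_areas <- function(x, ...) {
  lab <- setNames(x$residues$res_label, x$residues$res_key)
  ch <- setNames(x$residues$chain, x$residues$res_key)
  x$pairs |>
    mutate(
      label_i = unname(lab[.data$res_i]), chain_i = unname(ch[.data$res_i]),
      label_j = unname(lab[.data$res_j]), chain_j = unname(ch[.data$res_j])
    ) |>
    select("res_i", "label_i", "chain_i", "res_j", "label_j", "chain_j",
           "area_ij", "area_ji", "area")
}

#' Contact-area matrix as a symmetric numeric matrix
#' @param x A `fn_contact_areas` object.
#' @return Symmetric matrix of symmetrised areas (A^2), zero diagonal,
#'   labelled by residue.
#' @export
area_matrix <- function(x) {
  stopifnot(inherits(x, "fn_contact_areas"))
  keys <- x$residues$res_key
  m <- matrix(0, length(keys), length(keys),
              dimnames = list(x$residues$res_label, x$residues$res_label))
  i <- match(x$pairs$res_i, keys)
  j <- match(x$pairs$res_j, keys)
  m[cbind(i, j)] <- x$pairs$area
  m[cbind(j, i)] <- x$pairs$area
  m
}

#' @export
autoplot.fn_contact_areas <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label_i, y = .data$label_j,
                                   fill = .data$area)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression("area (" * ring(A)^2 * ")")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
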