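#' Parameters for geometric hydrogen-bond detection
#'
#' The Baker-Hubbard criterion: a donor-H...acceptor triple is a
#' hydrogen bond when the donor-H-acceptor angle exceeds `theta_min` and
#' the H...acceptor distance is below `d_max`.
#'
#' @param theta_min Minimum donor-H-acceptor angle in degrees (default
#'   120, strict).
#' @param d_max Maximum H...acceptor distance in Angstrom (default 2.5,
#'   strict).
#' @param scope `"sidechain-only"` (default): both donor and acceptor
#'   must be sidechain atoms; `"all"` includes backbone.
#' @return A list of class `fn_hbond_params`.
#' @export
hbond_params <- function(theta_min = 120, d_max = 2.5,
                         scope = c("sidechain-only", "all")) {
  if (!is.numeric(theta_min) || theta_min <= 0 || theta_min >= 180) {
    abort("`theta_min` must be in (0, 180)")
  }
  if (!is.numeric(d_max) || d_max <= 0) abort("`d_max` must be > 0")
  structure(list(theta_min = theta_min, d_max = d_max,
                 scope = match.arg(scope)),
            class = "fn_hbond_params")
}

backbone_names <- c("N", "CA", "C", "O", "OXT")

# sidechain donor definitions: fixed pH-7 protonation states
# type: hydroxyl (1 rotatable H), sp3 (3 staggered H), bisector (1 in-plane
# H), sp2pair (2 in-plane H with a torsion reference atom)
donor_rules <- function() {
  list(
    list(resid = "SER", donor = "OG", type = "hydroxyl", parent = "CB",
         grand = "CA", h = "HG", len = 0.96),
    list(resid = "THR", donor = "OG1", type = "hydroxyl", parent = "CB",
         grand = "CA", h = "HG1", len = 0.96),
    list(resid = "TYR", donor = "OH", type = "hydroxyl", parent = "CZ",
         grand = "CE1", h = "HH", len = 0.96),
    list(resid = "LYS", donor = "NZ", type = "sp3", parent = "CE",
         grand = "CD", h = c("HZ1", "HZ2", "HZ3"), len = 1.01),
    list(resid = "ARG", donor = "NE", type = "bisector",
         nb = c("CD", "CZ"), h = "HE", len = 1.01),
    list(resid = "ARG", donor = "NH1", type = "sp2pair", parent = "CZ",
         ref = "NE", h = c("HH11", "HH12"), len = 1.01),
    list(resid = "ARG", donor = "NH2", type = "sp2pair", parent = "CZ",
         ref = "NE", h = c("HH21", "HH22"), len = 1.01),
    list(resid = "ASN", donor = "ND2", type = "sp2pair", parent = "CG",
         ref = "OD1", h = c("HD21", "HD22"), len = 1.01),
    list(resid = "GLN", donor = "NE2", type = "sp2pair", parent = "CD",
         ref = "OE1", h = c("HE21", "HE22"), len = 1.01),
    list(resid = "TRP", donor = "NE1", type = "bisector",
         nb = c("CD1", "CE2"), h = "HE1", len = 1.01)
  )
}

#' Add polar sidechain hydrogens at fixed pH-7 protonation states
#'
#' Deterministic geometric protonation: lysine ammonium (3 H), arginine
#' guanidinium (5 H), Ser/Thr/Tyr hydroxyls (1 H), Asn/Gln amides (2 H),
#' Trp indole (1 H); Asp/Glu carboxylates stay deprotonated and His is
#' assigned the single neutral tautomer (ND1 or NE2) that maximises the
#' count of nearby hydrogen-bond partners, preferring NE2 on ties.
#' N-H bonds are 1.01 A, O-H bonds 0.96 A with ideal sp2/sp3 angles;
#' rotatable hydroxyl hydrogens are oriented toward the nearest acceptor
#' within 3.5 A, otherwise staggered. Donors that already carry a
#' hydrogen (within 1.2 A) are left unchanged, so externally protonated
#' files pass through untouched.
#'
#' @param structure A structure tibble with standard atom names.
#' @return The structure with added hydrogens (element "H"); added atoms
#'   get fresh serial numbers at the end of the table.
#' @export
#' @examples
#' s <- read_structure(text = make_pair("SER", "ASP", 2.8))
#' sp <- protonate(s)
#' sum(sp$element == "H")
protonate <- function(structure) {
  atoms <- as_tibble(structure)
  xyz_of <- function(rows, nm) {
    i <- which(rows$name == nm)[1]
    if (is.na(i)) return(NULL)
    c(rows$x[i], rows$y[i], rows$z[i])
  }
  # possible acceptor positions for hydroxyl orientation / His tautomer
  acc_all <- atoms[atoms$is_heavy & atoms$element %in% c("N", "O"), ,
                   drop = FALSE]
  h_atoms <- atoms[!atoms$is_heavy, , drop = FALSE]

  has_h <- function(pos) {
    if (nrow(h_atoms) == 0) return(FALSE)
    any((h_atoms$x - pos[1])^2 + (h_atoms$y - pos[2])^2 +
          (h_atoms$z - pos[3])^2 <= 1.2^2)
  }
  nearby_partners <- function(pos, own_key) {
    a <- acc_all[acc_all$res_key != own_key, , drop = FALSE]
    sum((a$x - pos[1])^2 + (a$y - pos[2])^2 + (a$z - pos[3])^2 <= 3.5^2)
  }

  place_hydroxyl <- function(g, p, o, own_key) {
    cand <- acc_all[acc_all$res_key != own_key, , drop = FALSE]
    d_o <- sqrt((cand$x - o[1])^2 + (cand$y - o[2])^2 + (cand$z - o[3])^2)
    cand <- cand[d_o <= 3.5, , drop = FALSE]
    taus <- seq(0, 355, by = 5)
    pos <- t(vapply(taus, function(t) place_dihedral(g, p, o, 0.96, 109.5, t),
                    numeric(3)))
    if (nrow(cand) == 0) {
      return(pos[taus == 180, ])
    }
    near <- which.min(sqrt((cand$x - o[1])^2 + (cand$y - o[2])^2 +
                             (cand$z - o[3])^2))
    target <- c(cand$x[near], cand$y[near], cand$z[near])
    d <- (pos[, 1] - target[1])^2 + (pos[, 2] - target[2])^2 +
      (pos[, 3] - target[3])^2
    pos[which.min(d), ]
  }

  new_h <- list()
  add_h <- function(rows, name, pos) {
    new_h[[length(new_h) + 1]] <<- tibble(
      name = name, element = "H", resid = rows$resid[1],
      chain = rows$chain[1], resno = rows$resno[1], insert = rows$insert[1],
      x = pos[1], y = pos[2], z = pos[3]
    )
  }

  rules <- donor_rules()
  for (key in unique(atoms$res_key)) {
    rows <- atoms[atoms$res_key == key, , drop = FALSE]
    rt <- rows$resid[1]

    for (rule in rules[vapply(rules, function(r) r$resid == rt, logical(1))]) {
      dpos <- xyz_of(rows, rule$donor)
      if (is.null(dpos)) {
        warn(paste0("residue ", rows$res_label[1],
                    " missing atom ", rule$donor, "; donor skipped"))
        next
      }
      if (has_h(dpos)) next
      ok <- TRUE
      if (rule$type == "hydroxyl") {
        g <- xyz_of(rows, rule$grand); p <- xyz_of(rows, rule$parent)
        if (is.null(g) || is.null(p)) ok <- FALSE
        if (ok) add_h(rows, rule$h, place_hydroxyl(g, p, dpos, key))
      } else if (rule$type == "sp3") {
        g <- xyz_of(rows, rule$grand); p <- xyz_of(rows, rule$parent)
        if (is.null(g) || is.null(p)) ok <- FALSE
        if (ok) {
          for (k in 1:3) {
            add_h(rows, rule$h[k],
                  place_dihedral(g, p, dpos, rule$len, 109.5,
                                 c(60, 180, 300)[k]))
          }
        }
      } else if (rule$type == "bisector") {
        n1 <- xyz_of(rows, rule$nb[1]); n2 <- xyz_of(rows, rule$nb[2])
        if (is.null(n1) || is.null(n2)) ok <- FALSE
        if (ok) {
          dir <- -(vunit(n1 - dpos) + vunit(n2 - dpos))
          add_h(rows, rule$h, dpos + rule$len * vunit(dir))
        }
      } else if (rule$type == "sp2pair") {
        p <- xyz_of(rows, rule$parent); ref <- xyz_of(rows, rule$ref)
        if (is.null(p) || is.null(ref)) ok <- FALSE
        if (ok) {
          add_h(rows, rule$h[1],
                place_dihedral(ref, p, dpos, rule$len, 120, 180))
          add_h(rows, rule$h[2],
                place_dihedral(ref, p, dpos, rule$len, 120, 0))
        }
      }
      if (!ok) {
        warn(paste0("residue ", rows$res_label[1],
                    " missing heavy atoms for ", rule$donor,
                    "; donor skipped"))
      }
    }

    if (rt == "HIS") {
      nd1 <- xyz_of(rows, "ND1"); ne2 <- xyz_of(rows, "NE2")
      cg <- xyz_of(rows, "CG"); ce1 <- xyz_of(rows, "CE1")
      cd2 <- xyz_of(rows, "CD2")
      if (is.null(nd1) || is.null(ne2) || is.null(cg) || is.null(ce1) ||
            is.null(cd2)) {
        warn(paste0("residue ", rows$res_label[1],
                    " incomplete imidazole; protonation skipped"))
      } else if (!has_h(nd1) && !has_h(ne2)) {
        h_nd1 <- nd1 + 1.01 * vunit(-(vunit(cg - nd1) + vunit(ce1 - nd1)))
        h_ne2 <- ne2 + 1.01 * vunit(-(vunit(cd2 - ne2) + vunit(ce1 - ne2)))
        if (nearby_partners(h_nd1, key) > nearby_partners(h_ne2, key)) {
          add_h(rows, "HD1", h_nd1)
        } else {
          add_h(rows, "HE2", h_ne2)
        }
      }
    }
  }

  if (length(new_h) > 0) {
    hh <- bind_rows(new_h)
    hh$serial <- max(atoms$serial) + seq_len(nrow(hh))
    hh$altloc <- ""
    hh$het <- FALSE
    atoms <- bind_rows(atoms, hh)
  }
  as_structure(atoms, source_id = attr(structure, "source_id"))
}

#' Detect hydrogen bonds with the Baker-Hubbard geometric criterion
#'
#' Donors are N-H and O-H groups (a hydrogen within covalent range,
#' 1.2 A, of a nitrogen or oxygen); acceptors are nitrogen and oxygen
#' atoms. A bond is reported once per (hydrogen, acceptor) pair when the
#' donor-H-acceptor angle exceeds `theta_min` and the H...acceptor
#' distance is below `d_max`. Intra-residue pairs are excluded; in the
#' default sidechain-only scope both partners must be sidechain atoms.
#'
#' @param structure A protonated structure tibble (see [protonate()]).
#' @param params A [hbond_params()].
#' @return A tibble with one row per hydrogen bond: donor residue/atom,
#'   hydrogen, acceptor residue/atom, `d` (A) and `theta` (degrees).
#' @export
detect_hbonds <- function(structure, params = hbond_params()) {
  atoms <- as_tibble(structure)
  h <- atoms[atoms$element == "H", , drop = FALSE]
  if (nrow(h) == 0) {
    abort("structure contains no hydrogens; run protonate() first")
  }
  heavy_no <- atoms[atoms$is_heavy & atoms$element %in% c("N", "O"), ,
                    drop = FALSE]

  # covalent parent of each hydrogen: nearest N/O within 1.2 A, same residue
  parent_idx <- vapply(seq_len(nrow(h)), function(i) {
    same <- heavy_no$res_key == h$res_key[i]
    if (!any(same)) return(NA_integer_)
    cand <- which(same)
    d2 <- (heavy_no$x[cand] - h$x[i])^2 + (heavy_no$y[cand] - h$y[i])^2 +
      (heavy_no$z[cand] - h$z[i])^2
    j <- which.min(d2)
    if (d2[j] <= 1.2^2) cand[j] else NA_integer_
  }, integer(1))

  keep_h <- !is.na(parent_idx)
  h <- h[keep_h, , drop = FALSE]
  parent <- heavy_no[parent_idx[keep_h], , drop = FALSE]

  acc <- heavy_no
  if (params$scope == "sidechain-only") {
    side_h <- !(parent$name %in% backbone_names)
    h <- h[side_h, , drop = FALSE]
    parent <- parent[side_h, , drop = FALSE]
    acc <- acc[!(acc$name %in% backbone_names), , drop = FALSE]
  }
  if (nrow(h) == 0 || nrow(acc) == 0) return(empty_hbond_tbl())

  out <- vector("list", nrow(h))
  for (i in seq_len(nrow(h))) {
    d <- sqrt((acc$x - h$x[i])^2 + (acc$y - h$y[i])^2 + (acc$z - h$z[i])^2)
    ok <- d < params$d_max & acc$res_key != h$res_key[i]
    if (!any(ok)) next
    cand <- which(ok)
    hp <- c(h$x[i], h$y[i], h$z[i])
    dp <- c(parent$x[i], parent$y[i], parent$z[i])
    theta <- vapply(cand, function(j) {
      angle_deg(dp, hp, c(acc$x[j], acc$y[j], acc$z[j]))
    }, numeric(1))
    pass <- theta > params$theta_min
    if (!any(pass)) next
    cand <- cand[pass]
    out[[i]] <- tibble(
      donor_res = parent$res_key[i], donor_label = parent$res_label[i],
      donor_atom = parent$name[i], h_atom = h$name[i],
      acceptor_res = acc$res_key[cand], acceptor_label = acc$res_label[cand],
      acceptor_atom = acc$name[cand], d = d[cand][pass],
      theta = theta[pass]
    )
  }
  bonds <- bind_rows(out)
  if (nrow(bonds) == 0) empty_hbond_tbl() else bonds
}

empty_hbond_tbl <- function() {
  tibble(
    donor_res = character(0), donor_label = character(0),
    donor_atom = character(0), h_atom = character(0),
    acceptor_res = character(0), acceptor_label = character(0),
    acceptor_atom = character(0), d = numeric(0), theta = numeric(0)
  )
}

# shared residue-network builder: connected components over residue pairs
partition_networks <- function(pairs_i, pairs_j, labels_i, labels_j,
                               resno_of) {
  nodes <- unique(c(pairs_i, pairs_j))
  if (length(nodes) == 0) {
    return(list(networks = tibble(network = integer(0), size = integer(0),
                                  members = list()),
                membership = setNames(integer(0), character(0))))
  }
  lab <- setNames(c(labels_i, labels_j), c(pairs_i, pairs_j))
  comp <- components_from_edges(
    length(nodes), cbind(match(pairs_i, nodes), match(pairs_j, nodes))
  )
  comp_ids <- unique(comp)
  info <- purrr::map(comp_ids, function(cc) {
    keys <- nodes[comp == cc]
    keys <- keys[order(resno_of(keys))]
    tibble(size = length(keys), members = list(unname(lab[keys])),
           member_keys = list(keys),
           first_resno = min(resno_of(keys)))
  }) |> bind_rows()
  ord <- order(-info$size, info$first_resno)
  info <- info[ord, , drop = FALSE]
  info$network <- seq_len(nrow(info))
  membership <- integer(length(nodes))
  names(membership) <- nodes
  for (k in seq_len(nrow(info))) {
    membership[info$member_keys[[k]]] <- info$network[k]
  }
  list(
    networks = info[, c("network", "size", "members", "member_keys")],
    membership = membership
  )
}

res_key_resno <- function(keys) {
  as.integer(vapply(strsplit(keys, "|", fixed = TRUE), `[[`, character(1), 2))
}

#' Partition residues into hydrogen-bond networks
#'
#' Two residues belong to the same network when a consecutive path of
#' hydrogen bonds connects them. A residue pair linked by several bonds
#' contributes a single edge; every bond is still listed.
#'
#' @param bonds A bond tibble from [detect_hbonds()].
#' @return An object of class `fn_networks`: list with `networks`
#'   (network id, size, member labels; ordered by size descending then
#'   first residue number), `bonds` (the input with a `network` column)
#'   and `kind = "hbond"`.
#' @export
build_networks <- function(bonds) {
  part <- partition_networks(bonds$donor_res, bonds$acceptor_res,
                             bonds$donor_label, bonds$acceptor_label,
                             res_key_resno)
  bonds$network <- unname(part$membership[bonds$donor_res])
  structure(list(networks = part$networks, bonds = bonds, kind = "hbond"),
            class = "fn_networks")
}

#' One-call hydrogen-bond network analysis
#'
#' Protonates the structure (donors already carrying hydrogens are left
#' unchanged) and returns the bond list partitioned into networks.
#'
#' @param structure A structure tibble.
#' @param params A [hbond_params()].
#' @return A `fn_networks` object; see [build_networks()].
#' @export
hbond_networks <- function(structure, params = hbond_params()) {
  build_networks(detect_hbonds(protonate(structure), params))
}

#' @export
print.fn_networks <- function(x, ...) {
  cat(if (x$kind == "hbond") "Hydrogen-bond" else "Salt-bridge",
      "networks:", nrow(x$networks), "network(s)\n")
  if (nrow(x$networks) > 0) print(tidy(x), ...)
  invisible(x)
}

#' @export
tidy.fn_networks <- function(x, ...) {
  tibble(
    network = x$networks$network,
    size = x$networks$size,
    residues = map_chr(x$networks$members, paste, collapse = ",")
  )
}

#' @export
glance.fn_networks <- function(x, ...) {
  tibble(
    n_networks = nrow(x$networks),
    largest_size = if (nrow(x$networks) > 0) max(x$networks$size) else 0L,
    n_bonds = nrow(x$bonds)
  )
}
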