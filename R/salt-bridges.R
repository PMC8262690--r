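#' Parameters for salt-bridge detection
#'
#' A salt bridge is an acidic sidechain oxygen (Asp OD1/OD2, Glu
#' OE1/OE2) and a basic sidechain nitrogen (Lys NZ, Arg NE/NH1/NH2)
#' strictly closer than `cutoff`. Histidine ring nitrogens and chain
#' termini can be opted in.
#'
#' @param cutoff Distance cutoff in Angstrom, strict less-than (default 4).
#' @param include_his Count HIS ND1/NE2 as basic? Default `FALSE`
#'   (neutral histidine at pH 7).
#' @param include_termini Count OXT (and the N-terminal amine) as
#'   charged? Default `FALSE`.
#' @return A list of class `fn_salt_params`.
#' @export
salt_bridge_params <- function(cutoff = 4, include_his = FALSE,
                               include_termini = FALSE) {
  if (!is.numeric(cutoff) || cutoff <= 0) abort("`cutoff` must be > 0")
  structure(list(cutoff = cutoff, include_his = include_his,
                 include_termini = include_termini),
            class = "fn_salt_params")
}

salt_atom_sets <- function(params) {
  acidic <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  basic <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
  if (params$include_his) basic$HIS <- c("ND1", "NE2")
  list(acidic = acidic, basic = basic)
}

#' Detect salt bridges from acidic-oxygen/basic-nitrogen distances
#'
#' All acidic-O against basic-N atom distances are computed; pairs
#' strictly below the cutoff are reported, one record per atom pair.
#' No hydrogens are required.
#'
#' @param structure A structure tibble.
#' @param params A [salt_bridge_params()].
#' @return A tibble with one row per bridging atom pair: acidic
#'   residue/atom, basic residue/atom and the distance in Angstrom.
#' @export
#' @examples
#' s <- read_structure(text = make_pair("LYS", "GLU", 3.5))
#' detect_salt_bridges(s)
detect_salt_bridges <- function(structure, params = salt_bridge_params()) {
  atoms <- as_tibble(structure)
  sets <- salt_atom_sets(params)
  pick <- function(defs, extra = character(0)) {
    sel <- rep(FALSE, nrow(atoms))
    for (rt in names(defs)) {
      sel <- sel | (atoms$resid == rt & atoms$name %in% defs[[rt]])
    }
    if (length(extra) > 0) sel <- sel | atoms$name %in% extra
    atoms[sel, , drop = FALSE]
  }
  acidic <- pick(sets$acidic,
                 if (params$include_termini) "OXT" else character(0))
  basic <- pick(sets$basic)
  if (params$include_termini && nrow(atoms) > 0) {
    first_res <- atoms$res_key[1]
    nterm <- atoms[atoms$res_key == first_res & atoms$name == "N", ,
                   drop = FALSE]
    basic <- bind_rows(basic, nterm)
  }
  if (nrow(acidic) == 0 || nrow(basic) == 0) return(empty_bridge_tbl())

  d <- sqrt(outer(acidic$x, basic$x, "-")^2 +
              outer(acidic$y, basic$y, "-")^2 +
              outer(acidic$z, basic$z, "-")^2)
  hit <- which(d < params$cutoff &
                 outer(acidic$res_key, basic$res_key, "!="),
               arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty_bridge_tbl())
  i <- hit[, 1]; j <- hit[, 2]
  tibble(
    acidic_res = acidic$res_key[i], acidic_label = acidic$res_label[i],
    acidic_atom = acidic$name[i],
    basic_res = basic$res_key[j], basic_label = basic$res_label[j],
    basic_atom = basic$name[j],
    distance = d[hit]
  ) |> arrange(.data$acidic_res, .data$basic_res, .data$distance)
}

empty_bridge_tbl <- function() {
  tibble(
    acidic_res = character(0), acidic_label = character(0),
    acidic_atom = character(0), basic_res = character(0),
    basic_label = character(0), basic_atom = character(0),
    distance = numeric(0)
  )
}

#' Group salt bridges into residue networks
#'
#' Connected components over the residues joined by bridges, ordered by
#' size descending then first residue number.
#'
#' @param bridges A bridge tibble from [detect_salt_bridges()].
#' @return A `fn_networks` object with `kind = "salt"`; the input
#'   bridges gain a `network` column (in `$bonds`).
#' @export
bridge_networks <- function(bridges) {
  part <- partition_networks(bridges$acidic_res, bridges$basic_res,
                             bridges$acidic_label, bridges$basic_label,
                             res_key_resno)
  bridges$network <- unname(part$membership[bridges$acidic_res])
  structure(list(networks = part$networks, bonds = bridges, kind = "salt"),
            class = "fn_networks")
}

#' One-call salt-bridge network analysis
#'
#' @param structure A structure tibble.
#' @param params A [salt_bridge_params()].
#' @return A `fn_networks` object; see [bridge_networks()].
#' @export
salt_bridge_networks <- function(structure, params = salt_bridge_params()) {
  bridge_networks(detect_salt_bridges(structure, params))
}
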