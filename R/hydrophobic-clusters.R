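#' Parameters for hydrophobic-cluster detection
#'
#' @param residue_types 3-letter codes defining the hydrophobic set
#'   (default ILE, LEU, VAL).
#' @param area_threshold Minimum symmetrised contact area (A^2) for two
#'   residues to count as in contact (default 10).
#' @param min_cluster_size Smallest reported cluster (default 2;
#'   singletons are never reported).
#' @param sidechain_only Restrict contact-area atoms to sidechains?
#'   Default `FALSE`: all heavy atoms of the hydrophobic residues
#'   participate, backbone included.
#' @return A list of class `fn_cluster_params`.
#' @export
cluster_params <- function(residue_types = c("ILE", "LEU", "VAL"),
                           area_threshold = 10, min_cluster_size = 2,
                           sidechain_only = FALSE) {
  if (!is.numeric(area_threshold) || area_threshold < 0) {
    abort("`area_threshold` must be >= 0")
  }
  if (!is.numeric(min_cluster_size) || min_cluster_size < 2) {
    abort("`min_cluster_size` must be >= 2")
  }
  structure(
    list(residue_types = toupper(residue_types),
         area_threshold = area_threshold,
         min_cluster_size = as.integer(min_cluster_size),
         sidechain_only = sidechain_only),
    class = "fn_cluster_params"
  )
}

#' Hydrophobic clusters from a contact-area matrix
#'
#' Thresholds the residue contact graph (edge when the symmetrised area
#' is at least `area_threshold`) and reports its connected components of
#' at least `min_cluster_size` residues, ordered by total area
#' descending. The total area of a cluster is the sum of its contact
#' areas, each contacting pair counted once.
#'
#' @param areas A `fn_contact_areas` from [contact_areas()].
#' @param params A [cluster_params()].
#' @return An object of class `fn_cluster_set`: list with `clusters`
#'   (one row per cluster: `cluster`, `size`, `members` (list column of
#'   residue labels), `total_area`, `n_contacts`, `area_per_contact`,
#'   `area_per_residue`), `contacts` (one row per contact with its
#'   cluster id) and `params`. `area_per_contact` is the statistic some
#'   reports label "area per residue"; both are returned.
#' @export
build_clusters <- function(areas, params = cluster_params()) {
  stopifnot(inherits(areas, "fn_contact_areas"))
  res <- areas$residues
  edges_tbl <- areas$pairs[areas$pairs$area >= params$area_threshold, ,
                           drop = FALSE]
  comp <- components_from_edges(
    nrow(res),
    cbind(match(edges_tbl$res_i, res$res_key),
          match(edges_tbl$res_j, res$res_key))
  )
  lab <- setNames(res$res_label, res$res_key)

  edges_tbl$cluster_raw <- comp[match(edges_tbl$res_i, res$res_key)]
  sizes <- table(comp)
  keep_comp <- as.integer(names(sizes)[sizes >= params$min_cluster_size])
  # components with >= 2 members but no edges cannot occur; guard anyway
  keep_comp <- intersect(keep_comp, unique(edges_tbl$cluster_raw))

  cl <- purrr::map(keep_comp, function(cc) {
    members_idx <- which(comp == cc)
    e <- edges_tbl[edges_tbl$cluster_raw == cc, , drop = FALSE]
    total <- sum(e$area)
    tibble(
      size = length(members_idx),
      members = list(res$res_label[members_idx]),
      member_keys = list(res$res_key[members_idx]),
      total_area = total,
      n_contacts = nrow(e),
      area_per_contact = total / nrow(e),
      area_per_residue = total / length(members_idx)
    )
  }) |> bind_rows()

  if (nrow(cl) == 0) {
    cl <- tibble(
      cluster = integer(0), size = integer(0), members = list(),
      member_keys = list(), total_area = numeric(0),
      n_contacts = integer(0), area_per_contact = numeric(0),
      area_per_residue = numeric(0)
    )
    contacts <- tibble(cluster = integer(0), res_i = character(0),
                       label_i = character(0), res_j = character(0),
                       label_j = character(0), area = numeric(0))
  } else {
    ord <- order(-cl$total_area)
    cl <- cl[ord, , drop = FALSE]
    cl$cluster <- seq_len(nrow(cl))
    cl <- cl[, c("cluster", "size", "members", "member_keys", "total_area",
                 "n_contacts", "area_per_contact", "area_per_residue")]
    cluster_of <- setNames(cl$cluster, keep_comp[ord])
    contacts <- edges_tbl |>
      mutate(
        cluster = unname(cluster_of[as.character(.data$cluster_raw)]),
        label_i = unname(lab[.data$res_i]),
        label_j = unname(lab[.data$res_j])
      ) |>
      filter(!is.na(.data$cluster)) |>
      arrange(.data$cluster) |>
      select("cluster", "res_i", "label_i", "res_j", "label_j", "area")
  }

  structure(
    list(clusters = cl, contacts = contacts, params = params,
         source_id = areas$source_id),
    class = "fn_cluster_set"
  )
}

#' One-call hydrophobic cluster analysis of a structure
#'
#' Computes ILV (by default) residue contact areas with the
#' surface-section algorithm and clusters them.
#'
#' @param structure A structure tibble from [read_structure()].
#' @param params A [cluster_params()].
#' @param contact A [contact_params()].
#' @param radii A [radius_table()].
#' @return A `fn_cluster_set`; see [build_clusters()].
#' @export
#' @examples
#' s <- read_structure(text = make_pair("LEU", "ILE", 4))
#' tidy(hydrophobic_clusters(s))
hydrophobic_clusters <- function(structure, params = cluster_params(),
                                 contact = contact_params(),
                                 radii = radius_table()) {
  atoms <- as_tibble(structure)
  if (params$sidechain_only) {
    atoms <- atoms[!(atoms$name %in% c("N", "CA", "C", "O", "OXT")), ,
                   drop = FALSE]
    structure <- as_structure(atoms, attr(structure, "source_id"))
  }
  res <- residue_table(structure)
  sel <- res$res_key[res$resid %in% params$residue_types]
  if (length(sel) == 0) {
    return(build_clusters(
      structure(list(pairs = tibble(res_i = character(0),
                                    res_j = character(0),
                                    area_ij = numeric(0),
                                    area_ji = numeric(0),
                                    area = numeric(0)),
                     residues = res[0, ], params = contact,
                     source_id = attr(structure, "source_id")),
                class = "fn_contact_areas"),
      params
    ))
  }
  build_clusters(contact_areas(structure, sel, contact, radii), params)
}

#' Per-cluster summary records
#'
#' @param clusters A `fn_cluster_set`.
#' @return A tibble with one row per cluster: members (comma-separated),
#'   size, total area, contact count, area per contact and area per
#'   residue.
#' @export
cluster_summary <- function(clusters) {
  stopifnot(inherits(clusters, "fn_cluster_set"))
  cl <- clusters$clusters
  tibble(
    cluster = cl$cluster,
    residues = map_chr(cl$members, paste, collapse = ","),
    size = cl$size,
    total_area = cl$total_area,
    n_contacts = cl$n_contacts,
    area_per_contact = cl$area_per_contact,
    area_per_residue = cl$area_per_residue
  )
}

#' @export
print.fn_cluster_set <- function(x, ...) {
  cat("Hydrophobic clusters:", nrow(x$clusters), "cluster(s)\n")
  if (nrow(x$clusters) > 0) print(cluster_summary(x), ...)
  invisible(x)
}

#' @export
tidy.fn_cluster_set <- function(x, ...) cluster_summary(x)

#' @export
glance.fn_cluster_set <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters),
    n_clustered_residues = sum(x$clusters$size),
    largest_area = if (nrow(x$clusters) > 0) max(x$clusters$total_area) else NA_real_,
    area_threshold = x$params$area_threshold
  )
}

#' @export
autoplot.fn_cluster_set <- function(object, ...) {
  df <- cluster_summary(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster),
                                   y = .data$total_area)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cluster",
                  y = expression("total contact area (" * ring(A)^2 * ")")) +
    ggplot2::theme_minimal()
}
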