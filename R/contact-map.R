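#' Residue contact map from minimum inter-atomic distances
#'
#' Entry (i, j) is the minimum distance between any two atoms of
#' residues i and j (heavy atoms only by default); the diagonal is 0.
#' Raw distances are returned; apply a threshold downstream if a binary
#' map is needed.
#'
#' @param structure A structure tibble.
#' @param include_hydrogens Include hydrogens in the minimum? Default
#'   `FALSE`.
#' @return An object of class `fn_contact_map`: list with `matrix`
#'   (symmetric, Angstrom, residue labels on dimnames) and `residues`.
#' @export
#' @examples
#' s <- read_structure(text = make_pair("LEU", "LEU", 5))
#' contact_matrix(s)$matrix
contact_matrix <- function(structure, include_hydrogens = FALSE) {
  atoms <- as_tibble(structure)
  if (!include_hydrogens) atoms <- atoms[atoms$is_heavy, , drop = FALSE]
  if (nrow(atoms) == 0) abort("structure has no atoms to map")
  res <- residue_table(as_structure(atoms, attr(structure, "source_id")))
  nres <- nrow(res)
  ridx <- match(atoms$res_key, res$res_key)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  by_res <- split(seq_len(nrow(atoms)), ridx)

  m <- matrix(0, nres, nres, dimnames = list(res$res_label, res$res_label))
  for (i in seq_len(nres)) {
    ai <- by_res[[as.character(i)]]
    for (j in seq_len(nres)) {
      if (j <= i) next
      aj <- by_res[[as.character(j)]]
      d2 <- outer(xyz[ai, 1], xyz[aj, 1], "-")^2 +
        outer(xyz[ai, 2], xyz[aj, 2], "-")^2 +
        outer(xyz[ai, 3], xyz[aj, 3], "-")^2
      m[i, j] <- m[j, i] <- sqrt(min(d2))
    }
  }
  structure(list(matrix = m, residues = res),
            class = "fn_contact_map")
}

#' @export
print.fn_contact_map <- function(x, ...) {
  cat("Contact map over", nrow(x$matrix), "residues (min inter-atom",
      "distance, A)\n")
  print(x$matrix[seq_len(min(6, nrow(x$matrix))),
                 seq_len(min(6, ncol(x$matrix))), drop = FALSE], ...)
  invisible(x)
}

#' Tidy a contact map into long format
#' @param x A `fn_contact_map`.
#' @param ... Unused.
#' @return Tibble with `res_i`, `res_j`, `distance` (all ordered pairs
#'   with i < j).
#' @export
tidy.fn_contact_map <- function(x, ...) {
  n <- nrow(x$matrix)
  idx <- which(upper.tri(x$matrix), arr.ind = TRUE)
  tibble(
    res_i = rownames(x$matrix)[idx[, 1]],
    res_j = colnames(x$matrix)[idx[, 2]],
    distance = x$matrix[idx]
  )
}

#' @export
autoplot.fn_contact_map <- function(object, ...) {
  m <- object$matrix
  df <- tibble(
    res_i = factor(rep(rownames(m), times = ncol(m)), levels = rownames(m)),
    res_j = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    distance = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$res_i, y = .data$res_j,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1,
                                  name = expression("d (" * ring(A) * ")")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
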