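#' Per-position charges of an amino-acid sequence
#'
#' Lys and Arg are +1, Asp and Glu are -1, every other standard residue
#' (including His, per the usual convention for these metrics) is 0.
#'
#' @param sequence One-letter amino-acid string.
#' @param his_positive Treat histidine as +1? Default `FALSE`.
#' @return Integer vector of charges in \{-1, 0, +1\}.
#' @export
#' @examples
#' charge_sequence("EKAA")
charge_sequence <- function(sequence, his_positive = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1 ||
        nchar(sequence) == 0) {
    abort("`sequence` must be a non-empty character scalar")
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
  bad <- which(!(aa %in% valid))
  if (length(bad) > 0) {
    abort(sprintf("unknown residue letter '%s' at position %d",
                  aa[bad[1]], bad[1]))
  }
  ch <- integer(length(aa))
  ch[aa %in% c("K", "R")] <- 1L
  ch[aa %in% c("D", "E")] <- -1L
  if (his_positive) ch[aa == "H"] <- 1L
  ch
}

#' Charge pattern of a sequence
#'
#' Bundles the per-position charges with the composition fractions used
#' by the patterning metrics: f+ and f- (fractions of positive and
#' negative residues), FCR = f+ + f-, NCPR = f+ - f- and the overall
#' charge asymmetry sigma = (f+ - f-)^2 / FCR.
#'
#' @inheritParams charge_sequence
#' @return An object of class `fn_charge_pattern`.
#' @export
charge_pattern <- function(sequence, his_positive = FALSE) {
  ch <- charge_sequence(sequence, his_positive)
  n <- length(ch)
  f_plus <- sum(ch == 1L) / n
  f_minus <- sum(ch == -1L) / n
  fcr_ <- f_plus + f_minus
  structure(
    list(
      sequence = toupper(sequence), charges = ch, length = n,
      f_plus = f_plus, f_minus = f_minus, fcr = fcr_,
      ncpr = f_plus - f_minus,
      sigma = if (fcr_ > 0) (f_plus - f_minus)^2 / fcr_ else 0
    ),
    class = "fn_charge_pattern"
  )
}

as_charge_pattern <- function(x) {
  if (inherits(x, "fn_charge_pattern")) x else charge_pattern(x)
}

#' Fraction of charged residues
#' @param x A sequence string or [charge_pattern()].
#' @return FCR in \[0, 1\].
#' @export
#' @examples
#' fcr("EKAA")
fcr <- function(x) as_charge_pattern(x)$fcr

# delta for a matrix of charge rows (A x L), vectorised over rows.
# Blobs are overlapping windows of length g, step 1.
delta_rows <- function(chmat, g) {
  L <- ncol(chmat)
  stopifnot(g >= 1, L >= g)
  nw <- L - g + 1L
  wmat <- matrix(0, L, nw)
  for (w in seq_len(nw)) wmat[w:(w + g - 1L), w] <- 1
  p <- (chmat == 1L) %*% wmat / g
  m <- (chmat == -1L) %*% wmat / g
  fcr_i <- p + m
  sig_i <- matrix(0, nrow(chmat), nw)
  nz <- fcr_i > 0
  sig_i[nz] <- ((p - m)[nz])^2 / fcr_i[nz]
  fp <- rowSums(chmat == 1L) / L
  fm <- rowSums(chmat == -1L) / L
  fcr_all <- fp + fm
  sigma <- ifelse(fcr_all > 0, (fp - fm)^2 / fcr_all, 0)
  rowSums((sig_i - sigma)^2) / nw
}

#' Blob-level charge-asymmetry deviation delta
#'
#' Over all overlapping windows ("blobs") of length `g`, the asymmetry
#' of each blob, sigma_i = (f+_i - f-_i)^2 / FCR_i (0 for uncharged
#' blobs), is compared with the whole-sequence asymmetry sigma; delta is
#' the mean squared deviation.
#'
#' @param x A sequence string or [charge_pattern()].
#' @param g Blob length (the metrics use 5 and 6).
#' @return delta_g (non-negative scalar).
#' @export
charge_delta <- function(x, g) {
  p <- as_charge_pattern(x)
  if (p$length < g) abort("sequence shorter than the blob size `g`")
  delta_rows(matrix(p$charges, nrow = 1), g)[1]
}

# distinct permutations of a multiset given counts of (+1, -1, 0)
multiset_permutation_count <- function(np, nm, n0) {
  exp(lgamma(np + nm + n0 + 1) - lgamma(np + 1) - lgamma(nm + 1) -
        lgamma(n0 + 1))
}

multiset_permutations <- function(np, nm, n0) {
  L <- np + nm + n0
  out <- matrix(0L, nrow = round(multiset_permutation_count(np, nm, n0)),
                ncol = L)
  row <- 0L
  cur <- integer(L)
  recurse <- function(pos, np, nm, n0) {
    if (pos > L) {
      row <<- row + 1L
      out[row, ] <<- cur
      return(invisible())
    }
    if (np > 0) { cur[pos] <<- 1L; recurse(pos + 1L, np - 1L, nm, n0) }
    if (nm > 0) { cur[pos] <<- -1L; recurse(pos + 1L, np, nm - 1L, n0) }
    if (n0 > 0) { cur[pos] <<- 0L; recurse(pos + 1L, np, nm, n0 - 1L) }
  }
  recurse(1L, np, nm, n0)
  out
}

# maximally segregated candidate arrangements. Two families cover the
# observed maximisers: (i) contiguous charge blocks with the neutral
# block split across the two ends, both charge orders; (ii) the neutral
# block in the middle with the charges split across the two ends in all
# proportions and end orders (for unbalanced compositions the maximiser
# can place same-sign charges at both termini).
block_candidates <- function(np, nm, n0) {
  cands <- list()
  add <- function(v) cands[[length(cands) + 1]] <<- v
  for (ord in list(c(1L, -1L), c(-1L, 1L))) {
    n1 <- if (ord[1] == 1L) np else nm
    n2 <- if (ord[1] == 1L) nm else np
    for (k in 0:n0) {
      add(c(rep(0L, k), rep(ord[1], n1), rep(ord[2], n2), rep(0L, n0 - k)))
    }
  }
  for (kp in 0:np) {
    for (km in 0:nm) {
      left <- list(c(rep(1L, kp), rep(-1L, km)), c(rep(-1L, km), rep(1L, kp)))
      right <- list(c(rep(1L, np - kp), rep(-1L, nm - km)),
                    c(rep(-1L, nm - km), rep(1L, np - kp)))
      for (l in left) for (r in right) add(c(l, rep(0L, n0), r))
    }
  }
  unique(cands)
}

#' Maximum delta over permutations of the composition
#'
#' The normaliser of kappa: the largest delta_g attainable by any
#' arrangement of the same charge composition. Computed exactly by
#' enumerating all distinct charge arrangements when their number is at
#' most `max_exhaustive`, otherwise as the best of the canonical
#' maximally-segregated candidate set (contiguous charge blocks in both
#' orders with the neutral block at every split position).
#'
#' @inheritParams charge_delta
#' @param max_exhaustive Enumeration limit (default 1e5 arrangements).
#' @return delta_max_g (non-negative scalar).
#' @export
charge_delta_max <- function(x, g, max_exhaustive = 1e5) {
  p <- as_charge_pattern(x)
  if (p$length < g) abort("sequence shorter than the blob size `g`")
  np <- sum(p$charges == 1L)
  nm <- sum(p$charges == -1L)
  n0 <- p$length - np - nm
  if (np + nm == 0) return(0)
  if (multiset_permutation_count(np, nm, n0) <= max_exhaustive) {
    arr <- multiset_permutations(np, nm, n0)
  } else {
    # heuristic lower bound; the observed arrangement is always included
    # so that delta / delta_max never exceeds 1
    arr <- rbind(do.call(rbind, block_candidates(np, nm, n0)),
                 p$charges)
  }
  max(delta_rows(arr, g))
}

#' Charge-segregation parameter kappa
#'
#' The mean of delta_g / delta_max_g for blob sizes g = 5 and 6. Kappa
#' is 0 for well-mixed sequences, 1 for a fully segregated block
#' arrangement, and undefined (`NA`) when the sequence carries no
#' charges or a normaliser is zero.
#'
#' @inheritParams charge_delta
#' @param max_exhaustive Passed to [charge_delta_max()].
#' @return kappa in \[0, 1\], or `NA_real_` when undefined.
#' @export
#' @examples
#' charge_kappa("EEEEEKKKKK") # 1
charge_kappa <- function(x, max_exhaustive = 1e5) {
  p <- as_charge_pattern(x)
  if (p$length < 6) abort("kappa requires a sequence of length >= 6")
  if (p$fcr == 0) return(NA_real_)
  ratios <- vapply(c(5L, 6L), function(g) {
    dmax <- charge_delta_max(p, g, max_exhaustive)
    if (dmax == 0) return(NA_real_)
    charge_delta(p, g) / dmax
  }, numeric(1))
  if (any(is.na(ratios))) return(NA_real_)
  mean(ratios)
}

#' Charge-patterning summary of a sequence
#'
#' @inheritParams charge_sequence
#' @return A one-row tibble with `length`, `f_plus`, `f_minus`, `fcr`,
#'   `ncpr`, `sigma` and `kappa`.
#' @export
#' @examples
#' charge_metrics("EKEKEKEKEK")
charge_metrics <- function(sequence, his_positive = FALSE) {
  p <- charge_pattern(sequence, his_positive)
  tibble(
    length = p$length, f_plus = p$f_plus, f_minus = p$f_minus,
    fcr = p$fcr, ncpr = p$ncpr, sigma = p$sigma,
    kappa = if (p$length >= 6) charge_kappa(p) else NA_real_
  )
}

#' @export
print.fn_charge_pattern <- function(x, ...) {
  cat("Charge pattern of", x$length, "residues: f+ =",
      signif(x$f_plus, 3), "f- =", signif(x$f_minus, 3), "FCR =",
      signif(x$fcr, 3), "\n")
  invisible(x)
}

#' @export
glance.fn_charge_pattern <- function(x, ...) charge_metrics(x$sequence)
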