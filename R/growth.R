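#' Pan- and core-genome growth curves
#'
#' For each sample size `k` from 1 to the number of accessions, accession
#' subsets of size `k` are drawn and the pan-genome size (genes present in
#' at least one subset member) and core size (genes present in every
#' member) are averaged over subsets. All `choose(N, k)` combinations are
#' enumerated when their number does not exceed `n_samples_per_size`;
#' otherwise that many distinct combinations are drawn uniformly at random
#' without replacement. The resulting mean curves are fitted by nonlinear
#' least squares to the customary pan-genome growth laws: a power law
#' `pan(n) = A * n^B + C` and an exponential decay
#' `core(n) = A * exp(B * n) + C`.
#'
#' @param presence Presence tibble.
#' @param n_samples_per_size Enumeration/sampling cap per sample size
#'   (default 500).
#' @param seed Integer seed for subset sampling.
#' @return An object of class `pav_growth`: a list with `curve` (tibble of
#'   `k`, `pan_mean`, `core_mean`, `n_samples`, `exhaustive`), `fit_pan`,
#'   `fit_core` (named coefficient vectors `A`, `B`, `C`, or `NULL` when
#'   the fit failed) and `fit_failed` flags.
#' @export
growth_curve <- function(presence, n_samples_per_size = 500, seed = 1) {
  if (n_samples_per_size < 1) abort("n_samples_per_size must be >= 1")
  m <- presence_matrix(presence)
  n_acc <- ncol(m)
  if (n_acc < 1L) abort("empty presence matrix")
  set.seed(stage_seed(seed, 97L))

  eval_subset <- function(idx) {
    sub <- m[, idx, drop = FALSE]
    pres <- rowSums(sub)
    c(pan = sum(pres > 0L), core = sum(pres == length(idx)))
  }

  rows <- lapply(seq_len(n_acc), function(k) {
    n_comb <- choose(n_acc, k)
    if (n_comb <= n_samples_per_size) {
      sets <- combn(n_acc, k, simplify = FALSE)
      exhaustive <- TRUE
    } else {
      sets <- list()
      seen <- character()
      while (length(sets) < n_samples_per_size) {
        s <- sort(sample.int(n_acc, k))
        key <- paste(s, collapse = ",")
        if (!key %in% seen) {
          seen <- c(seen, key)
          sets[[length(sets) + 1L]] <- s
        }
      }
      exhaustive <- FALSE
    }
    vals <- vapply(sets, eval_subset, numeric(2))
    tibble(k = k, pan_mean = mean(vals["pan", ]),
           core_mean = mean(vals["core", ]),
           n_samples = length(sets), exhaustive = exhaustive)
  })
  curve <- bind_rows(rows)

  g_total <- nrow(m)
  fit_one <- function(formula, start) {
    tryCatch(
      coef(minpack.lm::nlsLM(formula, data = curve, start = start,
                             control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL
    )
  }
  fit_pan <- fit_one(pan_mean ~ A * k^B + C,
                     list(A = g_total, B = 0.5, C = 0))
  fit_core <- fit_one(core_mean ~ A * exp(B * k) + C,
                      list(A = g_total, B = -0.5, C = 0))

  structure(list(curve = curve, fit_pan = fit_pan, fit_core = fit_core,
                 fit_failed = c(pan = is.null(fit_pan),
                                core = is.null(fit_core)),
                 n_genes = g_total, n_accessions = n_acc),
            class = "pav_growth")
}

#' @export
print.pav_growth <- function(x, ...) {
  cat(sprintf("Pan/core growth curve over %d accessions, %d genes\n",
              x$n_accessions, x$n_genes))
  cat(sprintf("  pan:  %d -> %.1f genes%s\n", as.integer(x$curve$pan_mean[1]),
              x$curve$pan_mean[nrow(x$curve)],
              if (x$fit_failed["pan"]) " (fit failed)" else ""))
  cat(sprintf("  core: %d -> %.1f genes%s\n", as.integer(x$curve$core_mean[1]),
              x$curve$core_mean[nrow(x$curve)],
              if (x$fit_failed["core"]) " (fit failed)" else ""))
  invisible(x)
}

#' Tidy a growth-curve fit
#'
#' @param x A `pav_growth` object.
#' @param ... Unused.
#' @return The per-sample-size curve as a tibble, with fitted values added
#'   when the corresponding model converged.
#' @export
tidy.pav_growth <- function(x, ...) {
  out <- x$curve
  if (!is.null(x$fit_pan)) {
    p <- x$fit_pan
    out$pan_fit <- p["A"] * out$k^p["B"] + p["C"]
  }
  if (!is.null(x$fit_core)) {
    p <- x$fit_core
    out$core_fit <- p["A"] * exp(p["B"] * out$k) + p["C"]
  }
  out
}

#' @rdname tidy.pav_growth
#' @export
glance.pav_growth <- function(x, ...) {
  cf <- function(f, n) if (is.null(f)) NA_real_ else unname(f[[n]])
  tibble(
    n_accessions = x$n_accessions,
    n_genes = x$n_genes,
    pan_A = cf(x$fit_pan, "A"), pan_B = cf(x$fit_pan, "B"),
    pan_C = cf(x$fit_pan, "C"),
    core_A = cf(x$fit_core, "A"), core_B = cf(x$fit_core, "B"),
    core_C = cf(x$fit_core, "C")
  )
}

#' Plot pan/core growth curves
#'
#' @param object A `pav_growth` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pav_growth <- function(object, ...) {
  d <- tidy(object) |>
    pivot_longer(dplyr::any_of(c("pan_mean", "core_mean")),
                 names_to = "set", values_to = "genes") |>
    mutate(set = ifelse(.data$set == "pan_mean", "pan-genome", "core genome"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$genes,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "number of accessions", y = "mean gene count",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
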