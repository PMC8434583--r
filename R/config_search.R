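#' Enumerate all admissible electrode configurations for an outer radius
#'
#' Every admissible geometry is a strictly increasing tuple of integer
#' boundaries `(disc, a1, b1, ..., an)` with the last ring's outer boundary
#' pinned at `outer_radius`, so for `n_rings` rings there are
#' `choose(outer_radius - 1, 2 * n_rings)` configurations: 5 at radius 6 and
#' 70 at radius 9 for a TCRE, and a single one at radius 5.
#'
#' @param outer_radius electrode radius in grid intervals.
#' @param n_rings number of concentric rings (2 for a TCRE).
#' @return A tibble with one row per configuration: `label` (compact
#'   `disc|a-b|a-b` notation), `disc_radius`, `ring<j>_inner`,
#'   `ring<j>_outer` columns, `outer_radius`, `n_rings`, and a `config`
#'   list-column of [cre_config()] objects.
#' @examples
#' enumerate_configs(6)
#' nrow(enumerate_configs(9))  # 70
#' @export
enumerate_configs <- function(outer_radius, n_rings = 2) {
  if (n_rings < 1 || outer_radius < 1) {
    stop("outer_radius and n_rings must be positive integers", call. = FALSE)
  }
  k <- 2 * n_rings
  if (outer_radius - 1 < k) {
    warning("outer_radius ", outer_radius, " admits no ", n_rings,
            "-ring configuration", call. = FALSE)
    combos <- matrix(numeric(0), nrow = 0, ncol = k)
  } else {
    combos <- t(utils::combn(outer_radius - 1, k))
  }
  configs <- lapply(seq_len(nrow(combos)),
                    function(i) as_cre_config(c(combos[i, ], outer_radius)))
  bounds <- cbind(combos, rep(outer_radius, nrow(combos)))
  colnames(bounds) <- c("disc_radius", paste0(
    "ring", rep(seq_len(n_rings), each = 2), c("_inner", "_outer")))
  out <- tibble::as_tibble(as.data.frame(bounds))
  out$label <- vapply(configs, format, "")
  out$outer_radius <- rep(outer_radius, nrow(out))
  out$n_rings <- rep(n_rings, nrow(out))
  out$config <- configs
  dplyr::relocate(out, "label")
}

#' Rank configurations by truncation-term coefficient
#'
#' Computes the exact lowest-remaining-order truncation coefficient for each
#' configuration and sorts ascending: the smallest coefficient marks the
#' most accurate Laplacian estimate. The percentage increase over the
#' optimum is formed from the exact coefficient ratio before any rounding,
#' then rounded half-up to 2 decimals; coefficients are also rendered
#' half-up to 3 decimals. Ties (none occur for radii 5-12) break
#' lexicographically on the boundary tuple.
#'
#' @param configs a tibble from [enumerate_configs()], or a list of
#'   [cre_config()] objects.
#' @return The input tibble with `rank`, `coefficient` (double),
#'   `coefficient_frac` (exact fraction string), `coefficient_3dp`,
#'   `pct_increase` columns, sorted by rank.
#' @examples
#' rank_configs(enumerate_configs(6))
#' @export
rank_configs <- function(configs) {
  if (!is.data.frame(configs)) {
    configs <- as.list(configs)
    lab <- vapply(configs, function(c) format(as_cre_config(c)), "")
    configs <- tibble::tibble(label = lab, config = lapply(configs, as_cre_config))
  }
  if (nrow(configs) == 0) stop("no configurations to rank", call. = FALSE)
  radii <- vapply(configs$config, function(c) c$outer_radius, 1)
  nr <- vapply(configs$config, function(c) c$n_rings, 1)
  if (length(unique(radii)) > 1 || length(unique(nr)) > 1) {
    stop("all configurations must share outer_radius and n_rings", call. = FALSE)
  }
  tc <- lapply(configs$config, truncation_coefficient)
  vals <- lapply(tc, `[[`, "value")
  num <- vapply(vals, function(v) v$num, 1)
  den <- vapply(vals, function(v) v$den, 1)
  # exact ascending order with lexicographic tie-break on boundaries
  bmat <- t(vapply(configs$config, config_boundaries,
                   numeric(2 * nr[1] + 1)))
  ord <- do.call(order, c(list(num / den), asplit(bmat, 2)))
  configs <- configs[ord, ]
  vals <- vals[ord]
  vmin <- vals[[1]]
  if (vmin$num == 0) stop("degenerate optimum: zero coefficient", call. = FALSE)
  pct <- vapply(vals, function(v) {
    rat_round(rational(100) * (v / vmin - rational(1)), 2)
  }, 1)
  configs$rank <- seq_len(nrow(configs))
  configs$coefficient <- vapply(vals, as.numeric, 1)
  configs$coefficient_frac <- vapply(vals, format, "")
  configs$coefficient_3dp <- vapply(vals, rat_decimal, "", digits = 3)
  configs$pct_increase <- pct
  out <- dplyr::relocate(configs, "rank", "label")
  class(out) <- c("cre_ranking", class(out))
  out
}

#' Select table rows in the style of a top/bottom report
#'
#' @param ranking a tibble from [rank_configs()].
#' @param top,bottom how many best/worst rows to keep (NULL = none).
#' @param named additionally keep these named configurations (labels matched
#'   against [named_config()] geometries at radius 9).
#' @return The filtered ranking, sorted by rank.
#' @export
select_ranking <- function(ranking, top = NULL, bottom = NULL, named = NULL) {
  keep <- logical(nrow(ranking))
  if (!is.null(top)) keep[ranking$rank <= top] <- TRUE
  if (!is.null(bottom)) keep[ranking$rank > nrow(ranking) - bottom] <- TRUE
  for (nm in named) {
    keep[ranking$label == format(named_config(nm))] <- TRUE
  }
  ranking[keep, ]
}

#' Check the general design principles on a ranked enumeration
#'
#' The exhaustive rankings obey five ordering principles: (1) the optimum
#' has a minimal disc, minimal middle-ring width and gaps, and a maximal
#' outer ring; (2) widening the outer ring beats leaving it narrower, other
#' boundaries equal; (3) widening the outer ring beats widening the middle
#' ring; (4) widening either ring beats widening the central disc; (5) with
#' the same total gap, placing the larger gap outward beats placing it
#' inward. Each is checked on the exact coefficients of the full
#' enumeration at the given radius.
#'
#' @param outer_radius electrode radius in intervals (>= 6 so that the
#'   comparison geometries exist).
#' @return A tibble with `principle`, `description`, `holds`.
#' @examples
#' cre_principles(9)
#' @export
cre_principles <- function(outer_radius) {
  if (outer_radius < 6) stop("principle checks need outer_radius >= 6", call. = FALSE)
  R <- outer_radius
  ranking <- rank_configs(enumerate_configs(R))
  coef_of <- function(b) {
    lab <- format(as_cre_config(b))
    ranking$coefficient[ranking$label == lab]
  }
  c_opt <- ranking$coefficient[1]
  tibble::tibble(
    principle = 1:5,
    description = c(
      "optimum = minimal disc/middle ring/gaps, maximal outer ring",
      "wider outer ring beats narrower, other boundaries equal",
      "widening outer ring beats widening middle ring",
      "widening a ring beats widening the central disc",
      "larger outer gap beats larger inner gap"),
    holds = c(
      ranking$label[1] == format(as_cre_config(c(1, 2, 3, 4, R))),
      c_opt < coef_of(c(1, 2, 3, 5, R)),
      c_opt < coef_of(c(1, 2, 4, 5, R)),
      coef_of(c(1, 2, 4, 5, R)) < coef_of(c(2, 3, 4, 5, R)) &&
        c_opt < coef_of(c(2, 3, 4, 5, R)),
      coef_of(c(1, 2, 3, 5, R)) < coef_of(c(1, 3, 4, 5, R))))
}

#' Coefficient-vs-rank plot of a ranked enumeration
#'
#' @param object a `cre_ranking` tibble from [rank_configs()].
#' @param ... unused.
#' @return A ggplot highlighting the optimal configuration.
#' @export
autoplot.cre_ranking <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$coefficient)) +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object[1, ], colour = "red") +
    ggplot2::labs(
      x = "rank",
      y = "|truncation coefficient| (order 6)",
      title = sprintf("TCRE configurations, outer radius %g",
                      object$config[[1]]$outer_radius)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
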