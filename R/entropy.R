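# Entropy-weight scoring: min-max normalization, characteristic
# proportions, information entropy, weights, and system/subsystem scores.

# long data -> counties x indicators matrix for one year
year_matrix <- function(data, year, counties, ids) {
  sub <- data[data$year == year, , drop = FALSE]
  m <- matrix(NA_real_, nrow = length(counties), ncol = length(ids),
              dimnames = list(counties, ids))
  m[cbind(match(sub$county, counties), match(sub$indicator, ids))] <- sub$value
  m
}

#' Min-max normalize an indicator panel
#'
#' Rescales every indicator to `[0, 1]`: positive-direction indicators by
#' `(x - min) / (max - min)`, negative-direction indicators by
#' `(max - x) / (max - min)`. With `pooling = "per_year"` (the default)
#' the max/min are taken within each year, so each year's best county
#' scores 1; `pooling = "pooled"` uses a common max/min across all years,
#' which makes cross-year score trends directly comparable.
#'
#' Constant (degenerate) columns carry no discriminating information: they
#' are normalized to 0 everywhere, flagged, and later receive entropy 1
#' and weight 0.
#'
#' @param panel an `indicator_panel`, see [as_indicator_panel()].
#' @param pooling normalization scope, `"per_year"` or `"pooled"`.
#' @return An object of class `normalized_panel`: list with `data` (long
#'   tibble of normalized values), `pooling`, `scheme`, `years`,
#'   `counties` and `degenerate` (tibble of flagged scope/indicator pairs).
#' @export
normalize_panel <- function(panel, pooling = c("per_year", "pooled")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(panel, "indicator_panel"))
  data <- panel$data
  if (any(!is.finite(data$value))) stop_esh("non-finite values in panel")

  scope_of <- if (pooling == "per_year") as.character(data$year)
              else rep("pooled", nrow(data))
  key <- paste(scope_of, data$indicator, sep = "\r")
  rng_min <- tapply(data$value, key, min)
  rng_max <- tapply(data$value, key, max)
  lo <- rng_min[key]
  hi <- rng_max[key]
  degen <- hi == lo

  dir <- panel$scheme$direction[match(data$indicator, panel$scheme$id)]
  norm <- ifelse(dir == "positive",
                 (data$value - lo) / (hi - lo),
                 (hi - data$value) / (hi - lo))
  norm[degen] <- 0

  degenerate <- unique(data.frame(scope = scope_of[degen],
                                  indicator = data$indicator[degen],
                                  stringsAsFactors = FALSE))
  if (nrow(degenerate) > 0) {
    if (all(paste(scope_of, data$indicator) %in%
            paste(degenerate$scope, degenerate$indicator)))
      stop_esh("all indicator columns are constant; nothing to normalize")
    warning("constant indicator column(s) normalized to 0: ",
            paste(unique(degenerate$indicator), collapse = ", "),
            call. = FALSE)
  }

  out <- data
  out$value <- as.numeric(norm)
  structure(
    list(data = out, pooling = pooling, scheme = panel$scheme,
         years = panel$years, counties = panel$counties,
         degenerate = tibble::as_tibble(degenerate)),
    class = "normalized_panel"
  )
}

#' Characteristic proportions of normalized indicators for one year
#'
#' Divides each normalized value by its indicator's column sum over the
#' counties of that year, so non-degenerate columns sum to 1. An all-zero
#' column yields all-zero proportions and is flagged via the `degenerate`
#' attribute.
#'
#' @param norm a `normalized_panel`.
#' @param year the year to extract.
#' @return A counties x indicators matrix of proportions with a
#'   `degenerate` attribute naming all-zero columns.
#' @export
indicator_proportions <- function(norm, year) {
  stopifnot(inherits(norm, "normalized_panel"))
  if (!year %in% norm$years) stop_esh("year ", year, " not in panel")
  x <- year_matrix(norm$data, year, norm$counties, norm$scheme$id)
  cs <- colSums(x)
  p <- sweep(x, 2, ifelse(cs > 0, cs, 1), "/")
  p[, cs == 0] <- 0
  attr(p, "degenerate") <- colnames(p)[cs == 0]
  p
}

#' Information entropy of indicator proportion columns
#'
#' Computes, per indicator, `E = -(1/ln m) * sum_i p * ln p` with the
#' convention `0 * ln 0 = 0`, where `m` is the number of counties.
#' Degenerate (all-zero) columns receive entropy 1: a column with no mass
#' discriminates nothing. Uniform columns also attain the maximum 1.
#'
#' @param p proportion matrix from [indicator_proportions()].
#' @return Named numeric vector of entropies in `[0, 1]`.
#' @export
entropy_values <- function(p) {
  m <- nrow(p)
  if (m < 2) stop_esh("entropy requires at least 2 counties (ln m > 0)")
  plogp <- p * log(p)
  plogp[p == 0] <- 0
  e <- -colSums(plogp) / log(m)
  degen <- attr(p, "degenerate")
  if (!is.null(degen)) e[degen] <- 1
  # clip tiny negative rounding of exactly-uniform columns
  pmin(pmax(e, 0), 1)
}

#' Entropy weights of the indicator system
#'
#' Converts entropies to weights `w_j = (1 - E_j) / sum_block (1 - E_j)`,
#' separately per year. With `scope = "per_system"` (default) the sum runs
#' over each system block (economy, society, healthcare), so each block's
#' weights sum to 1 and each system score lands in `[0, 1]` as the CCD
#' grade scale presumes. `scope = "global"` normalizes across all
#' indicators instead.
#'
#' @param norm a `normalized_panel`.
#' @param scope `"per_system"` or `"global"`.
#' @param shift optional nonnegative constant added to normalized values
#'   before the proportion step, for replicating shifted entropy variants
#'   (default 0; min-max output is already nonnegative).
#' @return A tibble `year, indicator, entropy, weight` (class
#'   `entropy_weights`) with the scope kept as an attribute.
#' @export
entropy_weights <- function(norm, scope = c("per_system", "global"),
                            shift = 0) {
  scope <- match.arg(scope)
  stopifnot(inherits(norm, "normalized_panel"), shift >= 0)
  scheme <- norm$scheme
  blocks <- if (scope == "per_system") split(scheme$id, scheme$system)
            else list(all = scheme$id)

  rows <- lapply(norm$years, function(yr) {
    p_in <- indicator_proportions(norm, yr)
    if (shift > 0) {
      x <- year_matrix(norm$data, yr, norm$counties, scheme$id) + shift
      cs <- colSums(x)
      p_in <- sweep(x, 2, cs, "/")
      attr(p_in, "degenerate") <- character(0)
    }
    e <- entropy_values(p_in)
    w <- rep(NA_real_, length(e))
    names(w) <- names(e)
    for (b in blocks) {
      d <- 1 - e[b]
      if (sum(d) <= 0)
        stop_esh("all indicators in a block have entropy 1 in year ", yr,
                 "; no information to weight")
      w[b] <- d / sum(d)
    }
    tibble::tibble(year = as.integer(yr), indicator = names(e),
                   entropy = unname(e), weight = unname(w))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "scope") <- scope
  class(out) <- c("entropy_weights", class(out))
  out
}

#' System and subsystem scores
#'
#' Computes, per county and year, the three comprehensive system scores
#' `U_EC` (economy, x1..x7), `U_SO` (society, x8..x12) and `U_HE`
#' (healthcare, x13..x20) as entropy-weighted sums of normalized
#' indicators, plus the eight subsystem condition values `Z1..Z8` as
#' unweighted means of each block's normalized indicators (these feed the
#' configurational analysis).
#'
#' @param norm a `normalized_panel`.
#' @param weights an `entropy_weights` tibble from [entropy_weights()].
#' @return A tibble `county, year, U_EC, U_SO, U_HE, Z1..Z8`.
#' @export
system_scores <- function(norm, weights) {
  stopifnot(inherits(norm, "normalized_panel"))
  if (!setequal(unique(weights$year), norm$years))
    stop_esh("weight years do not match panel years")
  scheme <- norm$scheme
  sys_cols <- c(economy = "U_EC", society = "U_SO", healthcare = "U_HE")
  subs <- sort(unique(scheme$subsystem))

  rows <- lapply(norm$years, function(yr) {
    x <- year_matrix(norm$data, yr, norm$counties, scheme$id)
    w <- weights[weights$year == yr, ]
    wv <- w$weight[match(colnames(x), w$indicator)]
    out <- tibble::tibble(county = rownames(x), year = as.integer(yr))
    for (s in names(sys_cols)) {
      ids <- system_indicators(scheme, s)
      out[[sys_cols[[s]]]] <-
        as.numeric(x[, ids, drop = FALSE] %*% wv[match(ids, colnames(x))])
    }
    for (z in subs) {
      ids <- subsystem_indicators(scheme, z)
      out[[z]] <- rowMeans(x[, ids, drop = FALSE])
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Score a panel end to end
#'
#' Convenience wrapper chaining [normalize_panel()], [entropy_weights()]
#' and [system_scores()].
#'
#' @inheritParams normalize_panel
#' @inheritParams entropy_weights
#' @return A list with elements `normalized`, `weights`, `scores`.
#' @export
score_panel <- function(panel, pooling = c("per_year", "pooled"),
                        scope = c("per_system", "global"), shift = 0) {
  norm <- normalize_panel(panel, pooling = pooling)
  w <- entropy_weights(norm, scope = scope, shift = shift)
  list(normalized = norm, weights = w, scores = system_scores(norm, w))
}
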