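# Synthetic cohorts with the location/scale structure of the reference
# registry, an optional low-rank "collinear" correlation preset, and an
# explicit contamination model standing in for hidden noise in designated
# parameters.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so generators never perturb user RNG flow.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Specify the marginal model of one parameter
#'
#' @param name Parameter name.
#' @param family \code{"normal"} or \code{"lognormal_shifted"} (a log-normal
#'   on \code{x - shift}, allowing negative support such as baseline-
#'   subtracted IgG titers).
#' @param groups Named list \code{list(EOP = c(mean, sd), LOP = ..., \,
#'   VALIDATION = ...)}; any subset of groups may be given.
#' @param shift Location shift for \code{lognormal_shifted}; every group
#'   mean must exceed it.
#' @param decimals Recorded measurement precision (0--6 decimal places);
#'   generated values are rounded to this precision, which is what gives
#'   the sample-entropy statistic its tie structure.
#' @return An object of class \code{parameter_spec}.
#' @export
parameter_spec <- function(name, family = c("normal", "lognormal_shifted"),
                           groups, shift = 0, decimals = 2) {
  family <- match.arg(family)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.list(groups) || !length(groups)) stop("groups must be a named list")
  bad <- setdiff(names(groups), GROUP_LEVELS)
  if (length(bad)) stop("unknown group(s) in spec '", name, "': ",
                        paste(bad, collapse = ", "))
  for (g in names(groups)) {
    ms <- groups[[g]]
    if (length(ms) != 2L || !all(is.finite(ms))) {
      stop("group '", g, "' of spec '", name, "' must be c(mean, sd)")
    }
    if (ms[2] <= 0) stop("SD must be strictly positive (spec '", name,
                         "', group '", g, "')")
    if (family == "lognormal_shifted" && ms[1] - shift <= 0) {
      stop("lognormal_shifted requires mean - shift > 0 (spec '", name,
           "', group '", g, "')")
    }
  }
  if (!(decimals %in% 0:6)) stop("decimals must be an integer in 0..6")
  structure(list(name = name, family = family, groups = groups,
                 shift = shift, decimals = as.integer(decimals)),
            class = "parameter_spec")
}

#' Specify a contamination (hidden-noise) model
#'
#' Operationalizes the hypothesis of random fluctuations in immunologic
#' parameters as a mixture displacement: each patient in a target group is
#' affected with probability \code{prop} independently per target
#' parameter, and an affected value is either displaced by
#' \code{+/- displacement} group standard deviations (\code{"bimodal"}) or
#' has its deviation from the group mean inflated by a log-normal factor
#' (\code{"heavy_tail"}).
#'
#' @param target_parameters Character vector of parameter names to perturb.
#' @param prop Mixture weight: fraction of affected patients, in (0, 1).
#' @param displacement Displacement in multiples of the group SD (bimodal)
#'   or tail-inflation strength (heavy_tail).
#' @param mode \code{"bimodal"} or \code{"heavy_tail"}.
#' @param target_groups Groups whose patients may be affected.
#' @return An object of class \code{contamination_spec}.
#' @export
contamination_spec <- function(target_parameters, prop = 0.3,
                               displacement = 3,
                               mode = c("bimodal", "heavy_tail"),
                               target_groups = "EOP") {
  mode <- match.arg(mode)
  if (!length(target_parameters)) stop("target_parameters must be non-empty")
  if (!is.numeric(prop) || prop <= 0 || prop >= 1) {
    stop("prop must lie strictly in (0, 1)")
  }
  if (!is.numeric(displacement) || displacement <= 0) {
    stop("displacement must be positive")
  }
  bad <- setdiff(target_groups, GROUP_LEVELS)
  if (length(bad)) stop("unknown target group(s): ", paste(bad, collapse = ", "))
  structure(list(target_parameters = unique(as.character(target_parameters)),
                 prop = prop, displacement = displacement, mode = mode,
                 target_groups = target_groups),
            class = "contamination_spec")
}

#' Assemble a generator configuration
#'
#' @param specs List of \code{\link{parameter_spec}} objects with unique
#'   names.
#' @param group_sizes Named integer vector of patients per group.
#' @param contamination Optional \code{\link{contamination_spec}} applied
#'   after generation.
#' @param seed Integer seed; identical configurations (seed included)
#'   produce bitwise-identical cohorts.
#' @param structure \code{"independent"} (parameters independent) or
#'   \code{"collinear"} (a seeded low-rank latent-factor model tying
#'   parameter blocks together, emulating the strong collinearity implied
#'   by a small normal subspace).
#' @param n_factors,group_separation,idio_var,loading_seed Collinear-preset
#'   knobs: number of latent factors, EOP-vs-LOP separation (in factor SD
#'   units) carried by the first factor, idiosyncratic variance per
#'   parameter, and the seed fixing the loading pattern.
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(specs, group_sizes = c(EOP = 68, LOP = 43,
                                                    VALIDATION = 51),
                             contamination = NULL, seed = 1L,
                             structure = c("independent", "collinear"),
                             n_factors = 11, group_separation = 1.2,
                             idio_var = 0.002, loading_seed = 42L) {
  structure_type <- match.arg(structure)
  if (!length(specs)) stop("specs must be non-empty")
  for (s in specs) {
    if (!inherits(s, "parameter_spec")) stop("specs must be parameter_spec objects")
  }
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate spec names")
  names(specs) <- nm
  bad <- setdiff(names(group_sizes), GROUP_LEVELS)
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  if (any(group_sizes < 1)) stop("group sizes must be positive")
  if (!is.null(contamination)) {
    stopifnot(inherits(contamination, "contamination_spec"))
    miss <- setdiff(contamination$target_parameters, nm)
    if (length(miss)) {
      stop("contamination targets not in specs: ", paste(miss, collapse = ", "))
    }
  }
  if (structure_type == "collinear" &&
      (n_factors < 1 || n_factors > length(specs))) {
    stop("n_factors must be between 1 and the number of parameters")
  }
  base::structure(
    list(specs = specs, group_sizes = group_sizes,
         contamination = contamination, seed = as.integer(seed),
         structure = structure_type, n_factors = as.integer(n_factors),
         group_separation = group_separation, idio_var = idio_var,
         loading_seed = as.integer(loading_seed)),
    class = "generator_config")
}

# Moment-matched log-normal parameters for a shifted target (mean, sd).
lognormal_pars <- function(mean, sd, shift) {
  m <- mean - shift
  sigma2 <- log1p((sd / m)^2)
  c(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}

# Family rule: treat a parameter as right-skewed (shifted log-normal) when
# a discovery group shows SD/|mean| > 0.8 or a mean-median gap above
# 0.25 SD; the validation group follows the discovery-inferred family.
infer_family <- function(row) {
  skew <- FALSE
  for (g in c("lop", "eop")) {
    m <- row[[paste0(g, "_mean")]]
    s <- row[[paste0(g, "_sd")]]
    md <- row[[paste0(g, "_median")]]
    if ((m != 0 && s / abs(m) > 0.8) || (m - md) > 0.25 * s) skew <- TRUE
  }
  if (skew) "lognormal_shifted" else "normal"
}

# Shift keeping the coefficient of variation of the log-normal part at or
# below `cv_cap` in every group: bounded kurtosis makes sample moments of
# heavy-tailed biomarkers (e.g. cytokines with SD several times the mean)
# recoverable at realistic n while preserving clear right skew.
infer_shift <- function(row, cv_cap = 0.5) {
  mins <- vapply(c("lop", "eop", "val"), function(g) {
    row[[paste0(g, "_mean")]] - row[[paste0(g, "_sd")]] / cv_cap
  }, 0)
  min(mins)
}

#' Packaged generator configuration for the 28-parameter reference panel
#'
#' Encodes all 28 registry parameters with per-group means and SDs taken
#' from the reference table, group sizes 68 EOP / 43 LOP / 51 VALIDATION,
#' a marginal family chosen by a skewness rule (shifted log-normal where
#' SD/|mean| > 0.8 or the mean-median gap exceeds 0.25 SD; normal
#' otherwise) and per-parameter recorded precision from the registry.
#'
#' @param structure \code{"independent"} or \code{"collinear"} (see
#'   \code{\link{generator_config}}).
#' @param contamination Optional \code{\link{contamination_spec}}.
#' @param seed Integer seed for generation.
#' @return A \code{\link{generator_config}} with 28 parameter specs.
#' @export
default_table2_config <- function(structure = c("independent", "collinear"),
                                  contamination = NULL, seed = 1L) {
  structure <- match.arg(structure)
  reg <- reference_parameters
  specs <- lapply(seq_len(nrow(reg)), function(i) {
    row <- reg[i, ]
    fam <- infer_family(row)
    shift <- if (fam == "lognormal_shifted") infer_shift(row) else 0
    parameter_spec(
      name = row$name, family = fam,
      groups = list(EOP = c(row$eop_mean, row$eop_sd),
                    LOP = c(row$lop_mean, row$lop_sd),
                    VALIDATION = c(row$val_mean, row$val_sd)),
      shift = shift, decimals = row$decimals)
  })
  generator_config(specs, contamination = contamination, seed = seed,
                   structure = structure)
}

# Draw n values from one spec for one group (before rounding).
draw_marginal <- function(spec, group, n) {
  ms <- spec$groups[[group]]
  if (is.null(ms)) stop("spec '", spec$name, "' has no group '", group, "'")
  if (spec$family == "normal") {
    stats::rnorm(n, ms[1], ms[2])
  } else {
    lp <- lognormal_pars(ms[1], ms[2], spec$shift)
    spec$shift + stats::rlnorm(n, lp["mu"], lp["sigma"])
  }
}

# Latent z-matrix (n x p, unit scale) for the collinear preset.  Carrier
# parameters own one factor each; the remaining parameters blend the group
# factor (factor 1) with two further factors under a seeded loading
# pattern, plus idiosyncratic noise idio_var.
collinear_z <- function(config, groups_vec) {
  p <- length(config$specs)
  n <- length(groups_vec)
  r <- config$n_factors
  tau2 <- config$idio_var
  reg <- reference_parameters
  nm <- names(config$specs)
  carrier <- reg$carrier[match(nm, reg$name)]
  carrier[is.na(carrier)] <- FALSE
  carriers <- which(carrier)
  if (length(carriers) != r) {
    # fall back: first r parameters act as carriers
    carriers <- seq_len(r)
  }
  # group factor: discovery-balanced offsets, pooled variance 1
  nE <- sum(groups_vec == "EOP"); nL <- sum(groups_vec == "LOP")
  wE <- nE / (nE + nL); wL <- 1 - wE
  delta <- config$group_separation
  between <- wE * wL * delta^2
  if (between >= 1) stop("group_separation too large for unit factor variance")
  sf <- sqrt(1 - between)
  offset <- ifelse(groups_vec == "EOP", wL * delta,
                   ifelse(groups_vec == "LOP", -wE * delta, 0))
  f <- matrix(stats::rnorm(n * r), n, r)
  f[, 1] <- offset + sf * f[, 1]
  # seeded loading pattern (fixed by loading_seed, independent of the
  # cohort seed so the preset is one reproducible object)
  W <- with_seed(config$loading_seed, {
    W <- matrix(0, p, r)
    # the strongly group-separated carrier owns the group factor; the
    # remaining carriers own factors 2..r
    il2 <- match("IL2", nm)
    if (!is.na(il2) && il2 %in% carriers) {
      carriers <- c(il2, setdiff(carriers, il2))
    }
    W[carriers[1], 1] <- 1
    for (j in seq_along(carriers)[-1]) W[carriers[j], j] <- 1
    # Non-carrier (residual) parameters are near-linear combinations of a
    # small set of shared axes: the group/severity factor plus the first
    # two response factors.  Residual columns at eigenvalue ~0 are almost
    # exactly predictable from the retained components, so the clean
    # residual cloud concentrates near a low-dimensional manifold -- the
    # regime in which residual-subspace anomaly detection operates.
    for (i in setdiff(seq_len(p), carriers)) {
      w <- numeric(r)
      w[1] <- stats::runif(1, 0.8, 0.95) * sample(c(-1, 1), 1)
      w[2:3] <- stats::runif(2, 0.1, 0.25) * sample(c(-1, 1), 2, TRUE)
      W[i, ] <- w / sqrt(sum(w^2))
    }
    W
  })
  z <- f %*% t(W) * sqrt(1 - tau2) +
    matrix(stats::rnorm(n * p, sd = sqrt(tau2)), n, p)
  colnames(z) <- nm
  z
}

#' Generate a synthetic cohort
#'
#' Draws a patient-by-parameter table from a \code{\link{generator_config}}.
#' Under \code{structure = "independent"} every parameter is sampled from
#' its configured marginal family per group, so sample moments converge to
#' the configured means/SDs.  Under \code{structure = "collinear"} patients
#' are driven by a low-rank latent-factor model (the first factor carrying
#' an EOP-vs-LOP contrast) and columns are placed on each parameter's raw
#' scale using discovery-pooled location and scale, emulating a cohort
#' whose correlation matrix has a small normal subspace.  All values are
#' rounded to the spec's recorded precision; contamination, if configured,
#' is injected afterwards via \code{\link{inject_contamination}}.
#'
#' @param config A \code{\link{generator_config}}.
#' @return A \code{\link{cohort_table}}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  sizes <- config$group_sizes
  groups_vec <- rep(names(sizes), times = sizes)
  ids <- unlist(lapply(names(sizes), function(g) {
    sprintf("%s_%03d", g, seq_len(sizes[[g]]))
  }), use.names = FALSE)
  nm <- names(config$specs)
  vals <- with_seed(config$seed, {
    if (config$structure == "collinear") {
      z <- collinear_z(config, groups_vec)
      reg <- reference_parameters
      out <- z
      for (j in seq_along(nm)) {
        row <- reg[match(nm[j], reg$name), ]
        if (is.na(row$name)) stop("collinear preset requires registry parameters")
        wts <- c(68, 43) / 111
        mu <- wts[1] * row$eop_mean + wts[2] * row$lop_mean
        sg <- wts[1] * row$eop_sd + wts[2] * row$lop_sd
        out[, j] <- mu + sg * z[, j]
      }
      out
    } else {
      out <- matrix(NA_real_, length(groups_vec), length(nm),
                    dimnames = list(NULL, nm))
      for (g in names(sizes)) {
        idx <- which(groups_vec == g)
        for (j in seq_along(nm)) {
          out[idx, j] <- draw_marginal(config$specs[[j]], g, length(idx))
        }
      }
      out
    }
  })
  for (j in seq_along(nm)) {
    vals[, j] <- round(vals[, j], config$specs[[j]]$decimals)
  }
  cohort <- cohort_table(vals, groups_vec, ids)
  if (!is.null(config$contamination)) {
    cohort <- inject_contamination(cohort, config$contamination,
                                   seed = config$seed + 1L)
  }
  cohort
}

# Smallest d in 0..6 such that rounding to d decimals leaves the column
# unchanged; used to restore recorded precision after contamination.
observed_decimals <- function(x) {
  for (d in 0:6) if (all(abs(x - round(x, d)) < 1e-9)) return(d)
  6L
}

#' Inject contamination into a cohort
#'
#' Applies the mixture displacement of a \code{\link{contamination_spec}}:
#' for every target parameter, each patient in a target group is affected
#' independently with probability \code{prop}; affected values are moved by
#' \code{+/- displacement} empirical group SDs (\code{"bimodal"}, sign
#' equiprobable) or have their deviation from the group mean inflated by a
#' log-normal factor (\code{"heavy_tail"}).  Untouched cells are returned
#' bit-identical; perturbed columns are re-rounded to their observed
#' recorded precision so contamination stays on the measurement grid.
#'
#' @param cohort A \code{\link{cohort_table}}.
#' @param spec A \code{\link{contamination_spec}} whose targets exist in
#'   the cohort.
#' @param seed Integer seed.
#' @return A new \code{\link{cohort_table}}.
#' @export
inject_contamination <- function(cohort, spec, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(spec, "contamination_spec"))
  miss <- setdiff(spec$target_parameters, cohort$parameters)
  if (length(miss)) {
    stop("contamination targets not in cohort: ", paste(miss, collapse = ", "))
  }
  vals <- cohort$values
  with_seed(seed, {
    for (pn in spec$target_parameters) {
      x <- vals[, pn]
      dec <- observed_decimals(x)
      for (g in spec$target_groups) {
        idx <- which(cohort$group == g)
        if (!length(idx)) next
        sd_g <- stats::sd(x[idx])
        mu_g <- mean(x[idx])
        hit <- idx[stats::runif(length(idx)) < spec$prop]
        if (!length(hit)) next
        if (spec$mode == "bimodal") {
          sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
          x[hit] <- x[hit] + sgn * spec$displacement * sd_g
        } else {
          infl <- exp(spec$displacement * abs(stats::rnorm(length(hit))) / 2)
          x[hit] <- mu_g + (x[hit] - mu_g) * infl
        }
      }
      vals[, pn] <- round(x, dec)
    }
  })
  cohort_table(vals, as.character(cohort$group), rownames(cohort$values))
}
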