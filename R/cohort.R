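# Synthetic cohort generation: group-structured discounters with lesion
# masks whose spatial placement is coupled to discounting behavior.

#' Lesion-geometry configuration
#'
#' Describes the synthetic voxel world: grid shape, voxel size, an
#' axis-aligned "critical region" box (the stand-in for the behaviorally
#' relevant anatomy), and the size range of the random box lesions. Lesions
#' with \code{"critical"} placement always intersect the critical region;
#' \code{"elsewhere"} lesions never do.
#'
#' Defaults: a 20 x 20 x 20 grid of 3 mm voxels with an 8 x 8 x 8 critical
#' box and lesion edges of 6-12 voxels, which puts typical lesion volumes at
#' the 20-30 cc scale of real stroke cohorts.
#'
#' @param grid_shape Three positive integers (voxels).
#' @param voxel_size_mm Three positive reals (mm).
#' @param critical_region 2 x 3 matrix, rows \code{lo} and \code{hi}:
#'   inclusive voxel-index bounds of the critical box.
#' @param lesion_size_range Min/max lesion edge length in voxels.
#' @return An object of class \code{lesion_geometry}.
#' @export
lesion_geometry <- function(grid_shape = c(20L, 20L, 20L),
                            voxel_size_mm = c(3, 3, 3),
                            critical_region = rbind(lo = c(6L, 6L, 6L),
                                                    hi = c(13L, 13L, 13L)),
                            lesion_size_range = c(6L, 12L)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("'grid_shape' must be 3 positive integers", call. = FALSE)
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 3L ||
      any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be 3 positive reals", call. = FALSE)
  cr <- matrix(as.integer(critical_region), nrow = 2L,
               dimnames = list(c("lo", "hi"), NULL))
  if (any(cr["lo", ] < 1L) || any(cr["hi", ] > grid_shape) ||
      any(cr["lo", ] > cr["hi", ]))
    stop("'critical_region' must be a nonempty box inside the grid",
         call. = FALSE)
  lsr <- as.integer(lesion_size_range)
  if (length(lsr) != 2L || lsr[1L] < 1L || lsr[2L] < lsr[1L] ||
      lsr[2L] > max(grid_shape))
    stop("invalid 'lesion_size_range'", call. = FALSE)
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 critical_region = cr, lesion_size_range = lsr),
            class = "lesion_geometry")
}

# does box [lo, hi] intersect the critical region?
box_hits_critical <- function(lo, hi, geometry) {
  cr <- geometry$critical_region
  all(lo <= cr["hi", ]) && all(hi >= cr["lo", ])
}

#' Generate a random box lesion
#'
#' Samples per-axis edge lengths uniformly from the geometry's size range
#' and a box position, then clips to the grid. \code{"critical"} placement
#' draws a box that fully covers the critical region (edge lengths are
#' raised to the region width where needed and the position is constrained
#' to contain it): the damage-behavior coupling is region-level, so
#' "critically lesioned" subjects are damaged throughout the region.
#' \code{"elsewhere"} placement rejection-samples until the box misses the
#' critical region entirely.
#'
#' @param geometry A \code{\link{lesion_geometry}}.
#' @param placement \code{"critical"} or \code{"elsewhere"}.
#' @return A nonempty binary \code{\link{lesion_mask}}.
#' @export
random_lesion_mask <- function(geometry,
                               placement = c("critical", "elsewhere")) {
  stopifnot(inherits(geometry, "lesion_geometry"))
  placement <- match.arg(placement)
  gs <- geometry$grid_shape
  cr <- geometry$critical_region
  lsr <- geometry$lesion_size_range
  if (placement == "critical") {
    width <- cr["hi", ] - cr["lo", ] + 1L
    size_lo <- pmax(lsr[1L], width)
    size_hi <- pmax(lsr[2L], width)
    size <- size_lo +
      vapply(size_hi - size_lo + 1L, sample.int, integer(1), size = 1L) - 1L
    # positions whose box contains the critical region and fits the grid
    lo_min <- pmax(1L, cr["hi", ] - size + 1L)
    lo_max <- pmin(cr["lo", ], gs - size + 1L)
    if (any(lo_min > lo_max))
      stop("grid too small for a lesion covering the critical region",
           call. = FALSE)
    lo <- lo_min +
      vapply(lo_max - lo_min + 1L, sample.int, integer(1), size = 1L) - 1L
    hi <- lo + size - 1L
    grid <- array(0L, dim = gs)
    grid[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] <- 1L
    return(lesion_mask(grid, geometry$voxel_size_mm))
  }
  for (attempt in seq_len(10000L)) {
    size <- lsr[1L] + sample.int(lsr[2L] - lsr[1L] + 1L, 3L,
                                 replace = TRUE) - 1L
    center <- vapply(gs, function(n) sample.int(n, 1L), integer(1))
    lo <- pmax(1L, center - (size - 1L) %/% 2L)
    hi <- pmin(gs, lo + size - 1L)
    lo <- pmax(1L, hi - size + 1L)
    if (!box_hits_critical(lo, hi, geometry)) {
      grid <- array(0L, dim = gs)
      grid[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] <- 1L
      return(lesion_mask(grid, geometry$voxel_size_mm))
    }
  }
  stop("could not place an 'elsewhere' lesion; geometry leaves no room",
       call. = FALSE)
}

#' Study-like group table
#'
#' The default three-group structure: an Insular-lesion group (n = 12,
#' critical placement), a Non-insular lesion control group (n = 13,
#' elsewhere placement), and healthy controls (n = 64, no lesion). Group
#' mean log10 discount rates per condition are set to the log10 of the
#' published group geometric means (Now: 0.011, 0.066, 0.026; Not-now:
#' 0.005, 0.018, 0.014 per day), and sd_log10_k = 0.5 matches the dispersion
#' implied by the published SD-to-geometric-mean ratios.
#'
#' @return A data frame with one row per group: \code{label}, \code{n},
#'   \code{mean_log10_k_now}, \code{mean_log10_k_notnow}, \code{sd_log10_k},
#'   \code{placement}.
#' @export
study_groups <- function() {
  data.frame(
    label = c("insular", "non_insular", "healthy_control"),
    n = c(12L, 13L, 64L),
    mean_log10_k_now = log10(c(0.011, 0.066, 0.026)),
    mean_log10_k_notnow = log10(c(0.005, 0.018, 0.014)),
    sd_log10_k = 0.5,
    placement = c("critical", "elsewhere", "none"),
    stringsAsFactors = FALSE
  )
}

#' Cohort configuration
#'
#' @param groups Data frame as returned by \code{\link{study_groups}}. A
#'   missing \code{mean_log10_k_notnow} column makes agents use one rate in
#'   both temporal frames.
#' @param beta Shared logistic choice-noise inverse temperature (1/euro);
#'   \code{Inf} for deterministic agents. Default 2.
#' @param model Discounting model generating behavior.
#' @param geometry A \code{\link{lesion_geometry}}.
#' @param effect_delta_log10_k Shift added to the mean log10 k of subjects
#'   with \code{"critical"} lesion placement (negative = shallower
#'   discounting when the critical region is damaged). Applied to both
#'   temporal frames. Default 0 (the default group table already carries
#'   its group differences in the means).
#' @param seed Default seed used by \code{\link{sample_cohort}}.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(groups = study_groups(), beta = 2,
                          model = c("hyperbolic", "exponential"),
                          geometry = lesion_geometry(),
                          effect_delta_log10_k = 0, seed = 1L) {
  model <- match.arg(model)
  stopifnot(is.data.frame(groups))
  needed <- c("label", "n", "mean_log10_k_now", "sd_log10_k", "placement")
  if (!all(needed %in% names(groups)))
    stop("'groups' must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (!"mean_log10_k_notnow" %in% names(groups))
    groups$mean_log10_k_notnow <- NA_real_
  if (any(groups$n < 1L)) stop("group n must be >= 1", call. = FALSE)
  if (any(groups$sd_log10_k < 0)) stop("sd_log10_k must be >= 0",
                                       call. = FALSE)
  if (!all(groups$placement %in% c("critical", "elsewhere", "none")))
    stop("placement must be critical/elsewhere/none", call. = FALSE)
  check_scalar(beta, "beta", nonneg = TRUE, allow_inf = TRUE)
  check_scalar(effect_delta_log10_k, "effect_delta_log10_k")
  check_scalar(seed, "seed")
  stopifnot(inherits(geometry, "lesion_geometry"))
  structure(list(groups = groups, beta = beta, model = model,
                 geometry = geometry,
                 effect_delta_log10_k = effect_delta_log10_k,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Sample a synthetic cohort
#'
#' Draws each subject's log10 discount rate from its group's normal law
#' (independently per temporal frame when the group table carries a
#' Not-now mean), generates a lesion mask according to the group's
#' placement, and shifts the mean log10 k of critical-placement subjects by
#' \code{effect_delta_log10_k}, coupling spatial damage to behavior.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param seed Integer seed; defaults to the seed stored in the config.
#'   Fixed seed implies an identical cohort on every call.
#' @return An object of class \code{td_cohort}: list with
#'   \code{subjects} (data frame: subject_id, group, placement, k_now,
#'   k_notnow, beta), \code{agents} (list of \code{\link{choice_agent}}),
#'   \code{masks} (list of \code{\link{lesion_mask}} or NULL), and
#'   \code{config}.
#' @export
sample_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  g <- config$groups
  n_total <- sum(g$n)
  rows <- vector("list", nrow(g))
  agents <- vector("list", n_total)
  masks <- vector("list", n_total)
  id <- 0L
  for (j in seq_len(nrow(g))) {
    for (s in seq_len(g$n[j])) {
      id <- id + 1L
      shift <- if (g$placement[j] == "critical")
        config$effect_delta_log10_k else 0
      lk_now <- stats::rnorm(1, g$mean_log10_k_now[j] + shift,
                             g$sd_log10_k[j])
      two_rates <- !is.na(g$mean_log10_k_notnow[j])
      lk_nn <- if (two_rates)
        stats::rnorm(1, g$mean_log10_k_notnow[j] + shift, g$sd_log10_k[j])
      else lk_now
      agents[[id]] <- choice_agent(
        config$model, k = 10^lk_now, beta = config$beta,
        k_notnow = if (two_rates) 10^lk_nn else NULL)
      # masks[id] <- list(...) so a NULL is stored, not deleted
      masks[id] <- list(if (g$placement[j] == "none") NULL
                        else random_lesion_mask(config$geometry,
                                                g$placement[j]))
      rows[[id]] <- data.frame(
        subject_id = sprintf("S%03d", id), group = g$label[j],
        placement = g$placement[j], k_now = 10^lk_now, k_notnow = 10^lk_nn,
        beta = config$beta, stringsAsFactors = FALSE)
    }
  }
  subjects <- do.call(rbind, rows)
  structure(list(subjects = subjects, agents = agents, masks = masks,
                 config = config),
            class = "td_cohort")
}

#' @export
print.td_cohort <- function(x, ...) {
  tab <- table(factor(x$subjects$group,
                      levels = unique(x$subjects$group)))
  cat(sprintf("<td_cohort> %d subjects (%s); %d with lesion masks\n",
              nrow(x$subjects),
              paste(sprintf("%s n=%d", names(tab), as.integer(tab)),
                    collapse = ", "),
              sum(!vapply(x$masks, is.null, TRUE))))
  invisible(x)
}
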