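# Thornthwaite PET and habitat drought indices.
#
# Monthly PET follows the classic Thornthwaite model: PET_j (cm/month) =
# 1.6 * L_j * (10 T_j / I)^a for months with T_j > 0, 0 otherwise, where I is
# the annual heat index, a its cubic polynomial, and L_j = D_j / 12 a
# latitudinal day-length adjustment. PET is converted to mm/month (x10) so the
# drought index DI_j = 100 (PET_j - P_j)/PET_j compares like with like
# (WorldClim precipitation is in mm).

# Ordinal day of the 15th of each month, fixed non-leap calendar.
.JDAY15 <- c(15L, 46L, 74L, 105L, 135L, 166L, 196L, 227L, 258L, 288L, 319L, 349L)

#' Construct a monthly climate record
#'
#' Bundles the per-accession inputs of the Thornthwaite chain: collection-site
#' latitude plus twelve monthly mean air temperatures and precipitation totals
#' (WorldClim-style monthly normals).
#'
#' @param accession_id Accession identifier.
#' @param latitude Latitude in signed sexagesimal degrees, in [-90, 90].
#' @param temperature Twelve monthly mean air temperatures (degrees C),
#'   January first.
#' @param precipitation Twelve monthly precipitation totals (mm), January
#'   first. Must be non-negative.
#' @return An object of class \code{monthly_climate}.
#' @examples
#' cl <- monthly_climate("acc1", 25, rep(20, 12), rep(30, 12))
#' drought_profile(cl)
#' @export
monthly_climate <- function(accession_id, latitude, temperature, precipitation) {
  if (length(temperature) != 12L || length(precipitation) != 12L)
    stop("temperature and precipitation must each have exactly 12 monthly values")
  if (anyNA(latitude) || abs(latitude) > 90)
    stop("latitude must lie in [-90, 90]")
  if (anyNA(precipitation) || any(precipitation < 0))
    stop("precipitation must be non-negative")
  structure(
    list(accession_id = as.character(accession_id),
         latitude = as.numeric(latitude),
         temperature = as.numeric(temperature),
         precipitation = as.numeric(precipitation)),
    class = "monthly_climate")
}

#' @export
print.monthly_climate <- function(x, ...) {
  cat("<monthly_climate> ", x$accession_id,
      "  lat ", format(x$latitude, digits = 5), "\n", sep = "")
  cat("  T (C): ", paste(format(x$temperature, digits = 3), collapse = " "), "\n", sep = "")
  cat("  P (mm): ", paste(format(x$precipitation, digits = 4), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Annual heat index
#'
#' \eqn{I = \sum_j (T_j/5)^{1.514}} over months with \eqn{T_j > 0}; months at
#' or below freezing contribute nothing, so an all-frozen year gives I = 0.
#'
#' @param temperature Twelve monthly mean temperatures (degrees C).
#' @return The annual heat index (dimensionless scalar).
#' @export
heat_index <- function(temperature) {
  if (length(temperature) != 12L)
    stop("temperature must have exactly 12 monthly values")
  pos <- temperature > 0
  sum((temperature[pos] / 5)^1.514)
}

#' Thornthwaite exponent
#'
#' The cubic polynomial of the annual heat index used as the PET exponent:
#' \eqn{a = 6.75\times10^{-7} I^3 - 7.71\times10^{-5} I^2 + 1.792\times10^{-2} I + 0.49239}.
#'
#' @param I Annual heat index, non-negative.
#' @return The exponent a.
#' @export
thorn_exponent <- function(I) {
  if (any(I < 0)) stop("heat index must be non-negative")
  6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
}

#' Solar declination for the 15th of a month
#'
#' Forsythe-style declination angle (radians) at the ordinal day of the 15th
#' of the month on a fixed non-leap calendar.
#'
#' @param month Integer month(s) 1..12.
#' @return Declination angle(s) A_j in radians.
#' @export
solar_declination <- function(month) {
  month <- as.integer(month)
  if (any(month < 1L | month > 12L)) stop("month must be in 1..12")
  J <- .JDAY15[month]
  asin(0.39795 * cos(0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (J - 186)))))
}

#' Day length
#'
#' Hours of daylight for the 15th of a month at a given latitude, with the
#' standard 0.8333-degree sun-altitude (refraction + solar disc) correction.
#' The arccos argument is clamped to [-1, 1], so polar day yields 24 h and
#' polar night 0 h.
#'
#' @param latitude Latitude in degrees.
#' @param month Integer month 1..12 (vectorised).
#' @return Day length(s) D_j in hours.
#' @export
day_length <- function(latitude, month) {
  if (abs(latitude) > 90) stop("latitude must lie in [-90, 90]")
  A <- solar_declination(month)
  lat <- latitude * pi / 180
  arg <- (sin(0.8333 * pi / 180) + sin(lat) * sin(A)) / (cos(lat) * cos(A))
  arg <- pmin(1, pmax(-1, arg))
  24 - (24 / pi) * acos(arg)
}

#' Monthly Thornthwaite potential evapotranspiration
#'
#' Computes the full Thornthwaite chain for one accession: heat index,
#' exponent, day length, radiation adjustment and monthly PET. PET is returned
#' in mm/month (the classic formula's cm are multiplied by 10) so it shares
#' units with precipitation.
#'
#' @param climate A \code{\link{monthly_climate}} object.
#' @return An object of class \code{drought_profile} with elements
#'   \code{pet} (mm/month), \code{heat_index}, \code{exponent},
#'   \code{day_length} (h), \code{radiation} (L_j = D_j/12) and an empty
#'   \code{di} slot (fill with \code{\link{monthly_di}}).
#' @export
monthly_pet <- function(climate) {
  stopifnot(inherits(climate, "monthly_climate"))
  Tm <- climate$temperature
  I <- heat_index(Tm)
  a <- thorn_exponent(I)
  D <- day_length(climate$latitude, 1:12)
  L <- D / 12
  pet <- numeric(12)
  pos <- Tm > 0
  if (any(pos)) # I > 0 whenever any T_j > 0
    pet[pos] <- 1.6 * L[pos] * (10 * Tm[pos] / I)^a * 10 # cm -> mm
  structure(
    list(accession_id = climate$accession_id,
         pet = pet, di = NULL,
         heat_index = I, exponent = a,
         day_length = D, radiation = L,
         aggregates = NULL),
    class = "drought_profile")
}

#' Monthly drought indices
#'
#' \eqn{DI_j = 100 (PET_j - P_j)/PET_j} where PET_j > 0 (both in mm); months
#' with no evaporative demand (PET_j = 0, i.e. frozen) take DI_j = 0, since
#' the ratio is undefined and there is no drought stress without demand.
#' DI_j is bounded above by 100 (precipitation is non-negative) and can be
#' arbitrarily negative in wet months.
#'
#' @param profile A \code{drought_profile} from \code{\link{monthly_pet}}.
#' @param climate The matching \code{\link{monthly_climate}} object.
#' @return The profile with its \code{di} slot filled.
#' @export
monthly_di <- function(profile, climate) {
  stopifnot(inherits(profile, "drought_profile"), inherits(climate, "monthly_climate"))
  P <- climate$precipitation
  if (any(P < 0)) stop("precipitation must be non-negative")
  pet <- profile$pet
  di <- numeric(12)
  pos <- pet > 0
  di[pos] <- 100 * (pet[pos] - P[pos]) / pet[pos]
  profile$di <- di
  profile
}

.TIMEFRAMES <- c("m3", "m6", "m12", "T1", "T2", "T3", "T4")

#' Aggregate monthly drought indices over a timeframe
#'
#' Accumulated windows (\code{m3}, \code{m6}, \code{m12}) average DI over 3,
#' 6 or 12 consecutive months starting at \code{anchor_month} (wrapping past
#' December); trimesters \code{T1}..\code{T4} are the fixed calendar quarters
#' Jan-Mar, Apr-Jun, Jul-Sep, Oct-Dec.
#'
#' @param profile A \code{drought_profile} with \code{di} filled.
#' @param timeframe One of \code{"m3","m6","m12","T1","T2","T3","T4"}.
#' @param anchor_month Starting month (1..12) for the accumulated windows.
#' @return The mean DI over the window.
#' @export
aggregate_di <- function(profile, timeframe, anchor_month = 1L) {
  stopifnot(inherits(profile, "drought_profile"))
  if (is.null(profile$di)) stop("profile has no drought indices; call monthly_di() first")
  if (!timeframe %in% .TIMEFRAMES)
    stop("unknown timeframe '", timeframe, "'; use one of ",
         paste(.TIMEFRAMES, collapse = ", "))
  anchor_month <- as.integer(anchor_month)
  if (anchor_month < 1L || anchor_month > 12L) stop("anchor_month must be in 1..12")
  months <- switch(timeframe,
    m3 = (anchor_month - 1L + 0:2) %% 12L + 1L,
    m6 = (anchor_month - 1L + 0:5) %% 12L + 1L,
    m12 = 1:12,
    T1 = 1:3, T2 = 4:6, T3 = 7:9, T4 = 10:12)
  mean(profile$di[months])
}

#' Full drought profile for one accession
#'
#' Convenience wrapper running PET, DI and all timeframe aggregates.
#'
#' @param climate A \code{\link{monthly_climate}} object.
#' @param anchor_month Anchor for the accumulated windows (see
#'   \code{\link{aggregate_di}}).
#' @return A \code{drought_profile} with \code{aggregates} filled (named
#'   vector over m3, m6, m12, T1..T4).
#' @export
drought_profile <- function(climate, anchor_month = 1L) {
  prof <- monthly_di(monthly_pet(climate), climate)
  prof$aggregates <- vapply(.TIMEFRAMES, function(tf)
    aggregate_di(prof, tf, anchor_month), numeric(1))
  prof
}

#' @export
print.drought_profile <- function(x, ...) {
  cat("<drought_profile> ", x$accession_id,
      "  I = ", format(x$heat_index, digits = 5),
      ", a = ", format(x$exponent, digits = 5), "\n", sep = "")
  cat("  PET (mm): ", paste(format(round(x$pet, 1)), collapse = " "), "\n", sep = "")
  if (!is.null(x$di))
    cat("  DI: ", paste(format(round(x$di, 1)), collapse = " "), "\n", sep = "")
  if (!is.null(x$aggregates)) {
    cat("  aggregates:\n")
    print(round(x$aggregates, 3))
  }
  invisible(x)
}

#' Habitat drought index table for a set of accessions
#'
#' Runs the Thornthwaite chain for every row of a climate table and returns
#' one row per accession with the seven timeframe indices.
#'
#' @param climate_table Data frame with columns \code{accession},
#'   \code{taxon}, \code{latitude} and monthly columns \code{t01..t12}
#'   (degrees C) and \code{p01..p12} (mm), as read by
#'   \code{\link{read_climate_csv}}.
#' @param anchor_month Anchor for accumulated windows.
#' @param scale If TRUE, z-scaled columns (suffix \code{_z}) are appended via
#'   \code{\link{scale_indices}}.
#' @return A data frame (\code{accession}, \code{taxon}, index columns).
#' @export
drought_index_table <- function(climate_table, anchor_month = 1L, scale = FALSE) {
  tcols <- sprintf("t%02d", 1:12)
  pcols <- sprintf("p%02d", 1:12)
  need <- c("accession", "taxon", "latitude", tcols, pcols)
  miss <- setdiff(need, names(climate_table))
  if (length(miss))
    stop("climate table is missing columns: ", paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(climate_table)), function(i) {
    cl <- monthly_climate(climate_table$accession[i], climate_table$latitude[i],
                          as.numeric(climate_table[i, tcols]),
                          as.numeric(climate_table[i, pcols]))
    drought_profile(cl, anchor_month)$aggregates
  })
  agg <- do.call(rbind, rows)
  out <- data.frame(accession = as.character(climate_table$accession),
                    taxon = as.character(climate_table$taxon),
                    agg, stringsAsFactors = FALSE, row.names = NULL)
  if (scale) out <- scale_indices(out)
  out
}

#' Z-scale drought index columns
#'
#' Appends, for every timeframe column present, a \code{_z} column centred to
#' mean 0 and scaled to sample (n-1) standard deviation 1 across accessions.
#' A zero-variance column scales to all zeros with a warning. Already-scaled
#' columns are left untouched, so the operation is idempotent.
#'
#' @param table A drought index table from \code{\link{drought_index_table}}.
#' @return The table with \code{_z} columns appended (or refreshed).
#' @export
scale_indices <- function(table) {
  idx <- intersect(.TIMEFRAMES, names(table))
  if (!length(idx)) stop("no timeframe index columns found")
  if (nrow(table) < 2L) stop("need at least 2 accessions to scale")
  for (cn in idx) {
    x <- table[[cn]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning("column '", cn, "' has zero variance; scaled column set to 0")
      z <- rep(0, length(x))
    } else {
      z <- (x - mean(x)) / s
    }
    table[[paste0(cn, "_z")]] <- z
  }
  table
}

#' Compare a drought index among taxonomic groups
#'
#' Screens each group for normality (Shapiro-Wilk at \code{alpha_normal}); if
#' every group looks normal the index is compared by one-way ANOVA with Tukey
#' HSD pairwise contrasts, otherwise by Kruskal-Wallis with pairwise Wilcoxon
#' rank-sum tests under Bonferroni correction. Groups with fewer than 2
#' members are excluded with a warning; groups too small for Shapiro-Wilk
#' (n < 3) force the non-parametric route.
#'
#' @param table A drought index table.
#' @param index Name of the index column to compare.
#' @param group Name of the grouping column (default \code{"taxon"}).
#' @param alpha_normal Significance level of the normality screen.
#' @return An object of class \code{group_comparison}: route taken, global
#'   test, per-pair p-values (adjusted for the Wilcoxon route).
#' @export
compare_groups <- function(table, index, group = "taxon", alpha_normal = 0.05) {
  if (!index %in% names(table)) stop("no column '", index, "' in table")
  if (!group %in% names(table)) stop("no column '", group, "' in table")
  x <- table[[index]]
  g <- as.character(table[[group]])
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding groups with fewer than 2 members: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% small)
    x <- x[keep]; g <- g[keep]
    sizes <- table(g)
  }
  if (length(sizes) < 2L) stop("need at least 2 groups with >= 2 members")
  gf <- factor(g)

  normal <- vapply(levels(gf), function(lev) {
    xi <- x[gf == lev]
    if (length(xi) < 3L || length(unique(xi)) == 1L) return(FALSE)
    stats::shapiro.test(xi)$p.value > alpha_normal
  }, logical(1))

  if (all(normal)) {
    fit <- stats::aov(x ~ gf)
    tk <- stats::TukeyHSD(fit)$gf
    pairs <- data.frame(pair = rownames(tk),
                        diff = tk[, "diff"],
                        p = tk[, "p adj"],
                        row.names = NULL, stringsAsFactors = FALSE)
    global <- summary(fit)[[1]]
    out <- list(route = "anova_tukey", index = index,
                normality_p_ok = normal,
                global = list(statistic = global[["F value"]][1],
                              p = global[["Pr(>F)"]][1]),
                pairs = pairs)
  } else {
    kw <- stats::kruskal.test(x, gf)
    # exact rank-sum p-values where wilcox.test supports them (no ties,
    # small n); ties fall back to the normal approximation silently
    pw <- suppressWarnings(
      stats::pairwise.wilcox.test(x, gf, p.adjust.method = "bonferroni"))
    pm <- pw$p.value
    pairs <- do.call(rbind, lapply(rownames(pm), function(r) {
      cc <- colnames(pm)[!is.na(pm[r, ])]
      if (!length(cc)) return(NULL)
      data.frame(pair = paste(r, cc, sep = "-"), diff = NA_real_,
                 p = pm[r, cc], row.names = NULL, stringsAsFactors = FALSE)
    }))
    out <- list(route = "kruskal_wilcoxon", index = index,
                normality_p_ok = normal,
                global = list(statistic = unname(kw$statistic), p = kw$p.value),
                pairs = pairs)
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> index '", x$index, "' via ",
      if (x$route == "anova_tukey") "ANOVA + Tukey HSD" else
        "Kruskal-Wallis + pairwise Wilcoxon (Bonferroni)", "\n", sep = "")
  cat("  global: statistic = ", format(x$global$statistic, digits = 4),
      ", p = ", format.pval(x$global$p, digits = 3), "\n", sep = "")
  print(x$pairs, digits = 4)
  invisible(x)
}
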