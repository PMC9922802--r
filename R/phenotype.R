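#' Total eggs per female over the scored days
#'
#' For each cross, per-female daily rates are averaged over vials within
#' each scored 24-h window and summed over the scored windows (no
#' interpolation between windows); the group value is the unweighted mean
#' over crosses. Aggregating cross means (rather than pooling vials) keeps
#' the replicate unit consistent with the cross-level randomization.
#'
#' @param table Egg-count table (see [validate_egg_table()]).
#' @param group Optional genotype label (TT/TG/GG) restricting the table;
#'   default uses all rows.
#' @return Named list: \code{per_cross} (named numeric) and \code{group}
#'   (mean over crosses).
#' @examples
#' tab <- data.frame(cross_id = "c1", genotype = "TT", vial_id = "v1",
#'                   day = c(3, 6), eggs = c(10, 6), n_females = 2)
#' total_eggs_per_female(tab)$group  # 8
#' @export
total_eggs_per_female <- function(table, group = NULL) {
  tab <- validate_egg_table(as.data.frame(table))
  if (!is.null(group)) {
    tab <- tab[tab$genotype_class == normalize_genotype(group), ,
               drop = FALSE]
    if (!nrow(tab))
      stop("no records for group ", group, call. = FALSE)
  }
  if (!nrow(tab)) stop("empty egg-count table", call. = FALSE)
  vial_day <- stats::aggregate(rate ~ cross_id + day, data = tab,
                               FUN = mean)
  per_cross <- tapply(vial_day$rate, vial_day$cross_id, sum)
  list(per_cross = per_cross, group = mean(per_cross))
}

#' Percent difference of a value relative to a reference
#'
#' \eqn{100 (a - b) / b}; positive when \code{value_a} exceeds the
#' reference \code{value_b} (reference second).
#'
#' @param value_a Value of interest.
#' @param value_b Reference value (> 0).
#' @return Percent difference.
#' @examples
#' percent_difference(11.78, 10)  # 17.8
#' @export
percent_difference <- function(value_a, value_b) {
  stopifnot(is.numeric(value_a), is.numeric(value_b))
  if (any(value_b <= 0))
    stop("reference value must be positive", call. = FALSE)
  100 * (value_a - value_b) / value_b
}

#' Egg volume from width and length
#'
#' Prolate-spheroid approximation \eqn{V = \pi/6 \cdot w^2 \ell}.
#'
#' @param width,length Egg width and length in mm (> 0).
#' @return Volume in mm^3.
#' @examples
#' egg_volume(0.2, 0.5)
#' @export
egg_volume <- function(width, length) {
  stopifnot(is.numeric(width), is.numeric(length))
  if (any(width <= 0) || any(length <= 0))
    stop("egg dimensions must be positive", call. = FALSE)
  if (any(width > length))
    warning("width exceeds length for some eggs; check orientation",
            call. = FALSE)
  pi / 6 * width^2 * length
}

#' Egg-to-adult viability
#'
#' Proportion of seeded eggs that yield emerged adults (40 eggs per vial by
#' default).
#'
#' @param emerged Number of emerged adults (0..\code{eggs_seeded}).
#' @param eggs_seeded Eggs seeded per vial (default 40).
#' @return Proportion in \[0, 1\].
#' @export
viability <- function(emerged, eggs_seeded = 40) {
  stopifnot(is.numeric(emerged), is.numeric(eggs_seeded))
  if (any(eggs_seeded <= 0)) stop("eggs_seeded must be > 0", call. = FALSE)
  if (any(emerged < 0) || any(emerged > eggs_seeded))
    stop("emerged must lie in [0, eggs_seeded]", call. = FALSE)
  emerged / eggs_seeded
}

#' Count-weighted mean event time per vial
#'
#' Used for both adult emergence (development time) and death under
#' starvation, where events are scored at discrete clock times (e.g. 08:00,
#' 14:00, 20:00). The vial value is the count-weighted mean of the scoring
#' times.
#'
#' @param times Numeric vector of scoring times (hours).
#' @param counts Events observed at each time (>= 0).
#' @return Mean event time, or an error when no event occurred.
#' @examples
#' mean_event_time(c(96, 104), c(1, 3))  # 102
#' @export
mean_event_time <- function(times, counts) {
  stopifnot(is.numeric(times), is.numeric(counts),
            length(times) == length(counts))
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (sum(counts) == 0)
    stop("no events scored; mean event time undefined for this vial",
         call. = FALSE)
  sum(times * counts) / sum(counts)
}

#' Per-fly dry weight from pooled weighing
#'
#' @param pool_mass Mass of the pool in mg.
#' @param pool_size Number of flies in the pool (default 6).
#' @return Mean per-fly mass in mg.
#' @export
dry_weight_per_fly <- function(pool_mass, pool_size = 6) {
  stopifnot(is.numeric(pool_mass), is.numeric(pool_size))
  if (any(pool_size < 1)) stop("pool_size must be >= 1", call. = FALSE)
  pool_mass / pool_size
}

#' Pairwise group effect sizes for a trait
#'
#' Convenience wrapper producing a tidy effects table
#' (trait, group_a, group_b, value_a, value_b, pct_diff) from named group
#' means.
#'
#' @param values Named numeric vector of group-level trait means.
#' @param trait Trait label.
#' @param reference Name of the reference group; when \code{NULL}, all
#'   ordered pairs are reported.
#' @return Data frame of effects.
#' @export
trait_effects <- function(values, trait, reference = NULL) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  gr <- names(values)
  pairs <- if (is.null(reference)) {
    subset(expand.grid(a = gr, b = gr, stringsAsFactors = FALSE), a != b)
  } else {
    data.frame(a = setdiff(gr, reference), b = reference,
               stringsAsFactors = FALSE)
  }
  data.frame(trait = trait, group_a = pairs$a, group_b = pairs$b,
             value_a = values[pairs$a], value_b = values[pairs$b],
             pct_diff = percent_difference(values[pairs$a],
                                           values[pairs$b]),
             row.names = NULL, stringsAsFactors = FALSE)
}
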