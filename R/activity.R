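#' Filter bumblebee transect records for the garden:farmland comparison
#'
#' Applies the two exclusion rules of the activity analysis: male records
#' are dropped (male foraging patterns and phenology differ from females),
#' and ambiguous sections — primarily farmland but secondarily garden — are
#' dropped entirely. Remaining records are strictly farmland or strictly
#' garden. The filter is idempotent; counts removed per rule are attached as
#' the `removed` attribute.
#'
#' @param records data.frame with columns `primary_habitat`,
#'   `secondary_habitat`, `length_km`, `species`, `caste`, `count` (and
#'   optionally `section_id`, `date`).
#' @param farmland_labels primary-habitat labels treated as farmland.
#' @return filtered data.frame with a normalized `habitat` column
#'   (`"farmland"` or `"garden"`).
#' @export
filter_transects <- function(records,
                             farmland_labels = c("farmland", "agricultural",
                                                 "arable", "pasture",
                                                 "grassland")) {
  bad_caste <- setdiff(unique(records$caste), c("worker", "queen", "male"))
  if (length(bad_caste) > 0)
    stop("unknown caste label(s): ", paste(bad_caste, collapse = ", "),
         call. = FALSE)
  if (any(records$length_km <= 0))
    stop("section lengths must be > 0", call. = FALSE)
  is_farm <- records$primary_habitat %in% farmland_labels
  is_gard <- records$primary_habitat == "garden"
  ambiguous <- is_farm & !is.na(records$secondary_habitat) &
    records$secondary_habitat == "garden"
  male <- records$caste == "male"
  keep <- (is_farm | is_gard) & !ambiguous & !male
  out <- records[keep, , drop = FALSE]
  out$habitat <- ifelse(out$primary_habitat == "garden", "garden", "farmland")
  attr(out, "removed") <- c(ambiguous_section = sum(ambiguous & !male),
                            male = sum(male),
                            other_habitat = sum(!is_farm & !is_gard & !male))
  out
}

# Unique-section effort table: km surveyed per habitat per month. Sections
# are the sampling unit; lengths are counted once per section, not once per
# species row.
.section_effort <- function(records) {
  key <- records$section_id %||%
    paste(records$date, records$primary_habitat, records$secondary_habitat,
          records$length_km)
  first <- !duplicated(key)
  data.frame(habitat = records$habitat[first],
             month = as.POSIXlt(records$date[first])$mon + 1L,
             length_km = records$length_km[first])
}

#' Bumblebee encounter rate per km of transect
#'
#' Total observations divided by total km of (unique) transect sections
#' surveyed in that habitat and month.
#'
#' @param records a filtered table from [filter_transects()].
#' @param habitat `"farmland"` or `"garden"`.
#' @param month month 1..12.
#' @param species species label, or `NULL` to pool all species.
#' @return bees per km (0 when sections were surveyed but nothing seen;
#'   `NA` when no transect length was surveyed, with a warning).
#' @export
activity_rate <- function(records, habitat, month, species = NULL) {
  eff <- .section_effort(records)
  km <- sum(eff$length_km[eff$habitat == habitat & eff$month == month])
  if (km <= 0) {
    warning(sprintf("no transect length surveyed in %s in month %d",
                    habitat, month))
    return(NA_real_)
  }
  m <- as.POSIXlt(records$date)$mon + 1L
  sel <- records$habitat == habitat & m == month
  if (!is.null(species)) sel <- sel & records$species == species
  sum(records$count[sel]) / km
}

#' Monthly garden:farmland activity ratios
#'
#' For each species and month (and a pooled all-species row), the garden
#' encounter rate divided by the farmland encounter rate. Ratios are missing
#' (`NA`) when the farmland rate is zero or a habitat was not surveyed —
#' never infinite. Optionally adds a nonparametric bootstrap confidence
#' interval, resampling transect sections with replacement.
#'
#' @param records a filtered table from [filter_transects()].
#' @param n_boot bootstrap draws for the CI (0 to skip).
#' @param conf confidence level.
#' @return data.frame (`activity_table`): month, species, garden_rate,
#'   farmland_rate, ratio, and optionally `lower`/`upper`.
#' @export
garden_farmland_ratio <- function(records, n_boot = 0, conf = 0.95) {
  months <- sort(unique(as.POSIXlt(records$date)$mon + 1L))
  species <- c(sort(unique(records$species)), "all")
  rate <- function(rec, habitat, month, sp) {
    suppressWarnings(activity_rate(rec, habitat, month,
                                   if (sp == "all") NULL else sp))
  }
  out <- expand.grid(month = months, species = species,
                     stringsAsFactors = FALSE)
  out$garden_rate <- mapply(function(m, s) rate(records, "garden", m, s),
                            out$month, out$species)
  out$farmland_rate <- mapply(function(m, s) rate(records, "farmland", m, s),
                              out$month, out$species)
  out$ratio <- ifelse(!is.na(out$farmland_rate) & out$farmland_rate > 0,
                      out$garden_rate / out$farmland_rate, NA_real_)
  if (n_boot > 0) {
    key <- records$section_id %||%
      paste(records$date, records$primary_habitat,
            records$secondary_habitat, records$length_km)
    idx_by_sec <- split(seq_along(key), key)
    secs <- names(idx_by_sec)
    draws <- replicate(n_boot, {
      pick <- sample(secs, length(secs), replace = TRUE)
      idx <- unlist(idx_by_sec[pick], use.names = FALSE)
      rec <- records[idx, , drop = FALSE]
      mapply(function(m, s) {
        g <- rate(rec, "garden", m, s); f <- rate(rec, "farmland", m, s)
        if (is.na(f) || f <= 0) NA_real_ else g / f
      }, out$month, out$species)
    })
    a <- (1 - conf) / 2
    qs <- apply(draws, 1, stats::quantile, probs = c(a, 1 - a),
                na.rm = TRUE)
    out$lower <- qs[1, ]; out$upper <- qs[2, ]
  }
  class(out) <- c("activity_table", "data.frame")
  out
}
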