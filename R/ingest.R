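#' @name vgi_ingest
#' @title Checklist aggregation to monthly visitation and richness series
#' @description
#' Turns raw citizen-science checklist records (one row per species entry on
#' a posted list) into the monthly series the count models consume: Birder
#' User Days (BuDs) -- distinct birder-date pairs at a hotspot, the
#' visitation proxy -- and species richness, both for all species and for a
#' freshwater-habitat "long list" subset.  Months with no checklists are
#' materialized as explicit zeros so every hotspot yields a complete 1..T
#' panel.
NULL

normalize_species <- function(x) casefold(trimws(x))

check_dates <- function(checklists) {
  d <- as.Date(checklists$date, optional = TRUE)
  bad <- which(is.na(d) & !is.na(checklists$date) & checklists$date != "")
  bad <- union(bad, which(is.na(checklists$date)))
  if (length(bad))
    stop("malformed date at checklist row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ...")
  d
}

#' @rdname vgi_ingest
#' @param checklists data frame with columns `checklist_id`, `birder_id`,
#'   `hotspot_id`, `date`, `species` (long format: one row per species entry).
#' @param hotspot hotspot id to aggregate.
#' @param epoch first day of month 1 of the study window.
#' @param n_months window length in months.
#' @return `aggregate_buds()`: data frame `(month_index, bud_count)` over
#'   the full window, where `bud_count` is the number of distinct
#'   (birder, date) pairs among the hotspot's checklists that month.  An
#'   unknown hotspot yields the all-zero series with a warning.
#' @export
aggregate_buds <- function(checklists, hotspot, epoch, n_months) {
  out <- data.frame(month_index = seq_len(n_months), bud_count = 0L)
  cl <- checklists[checklists$hotspot_id == hotspot, , drop = FALSE]
  if (nrow(cl) == 0L) {
    warning("no checklists for hotspot ", hotspot, "; returning zero series")
    return(out)
  }
  d <- check_dates(cl)
  midx <- date_month_index(d, epoch)
  keep <- midx >= 1L & midx <= n_months
  if (!any(keep)) return(out)
  pairs <- unique(data.frame(birder = cl$birder_id[keep], date = d[keep],
                             midx = midx[keep]))
  cnt <- table(factor(pairs$midx, levels = seq_len(n_months)))
  out$bud_count <- as.integer(cnt)
  out
}

#' @rdname vgi_ingest
#' @param longlist optional character vector of species names flagged as
#'   using freshwater or freshwater-edge habitat; matching is exact after
#'   trimming and case-folding.
#' @return `monthly_richness()`: data frame `(month_index, richness_all,
#'   richness_water)`, counts of unique species on all checklists posted
#'   from the hotspot that month (`richness_water` restricted to the long
#'   list; 0 everywhere when `longlist` is `NULL`).
#' @export
monthly_richness <- function(checklists, hotspot, epoch, n_months,
                             longlist = NULL) {
  out <- data.frame(month_index = seq_len(n_months), richness_all = 0L,
                    richness_water = 0L)
  cl <- checklists[checklists$hotspot_id == hotspot, , drop = FALSE]
  if (nrow(cl) == 0L) return(out)
  d <- check_dates(cl)
  midx <- date_month_index(d, epoch)
  keep <- midx >= 1L & midx <= n_months
  if (!any(keep)) return(out)
  sp <- normalize_species(cl$species[keep])
  ll <- if (is.null(longlist)) character() else
    unique(normalize_species(longlist))
  by_month <- split(sp, factor(midx[keep], levels = seq_len(n_months)))
  out$richness_all <- vapply(by_month, function(s) length(unique(s)),
                             integer(1))
  out$richness_water <- vapply(by_month, function(s)
    length(intersect(unique(s), ll)), integer(1))
  out
}

#' @rdname vgi_ingest
#' @return `descriptive_stats()`: list of totals (checklists, birders,
#'   visit days, hotspots) and means (postings per birder, species per list,
#'   visit days per birder, hotspots per birder); an empty input returns a
#'   sentinel with `empty = TRUE` and `NA` statistics.
#' @export
descriptive_stats <- function(checklists) {
  if (is.null(checklists) || nrow(checklists) == 0L) {
    out <- list(empty = TRUE, n_checklists = 0L, n_birders = 0L,
                n_visit_days = 0L, n_hotspots = 0L,
                postings_per_birder = NA_real_, species_per_list = NA_real_,
                visit_days_per_birder = NA_real_,
                hotspots_per_birder = NA_real_)
    class(out) <- "bud_descriptives"
    return(out)
  }
  d <- check_dates(checklists)
  lists <- unique(data.frame(id = checklists$checklist_id,
                             birder = checklists$birder_id,
                             hotspot = checklists$hotspot_id, date = d))
  visits <- unique(lists[c("birder", "hotspot", "date")])
  n_birders <- length(unique(lists$birder))
  sp_per_list <- tapply(normalize_species(checklists$species),
                        checklists$checklist_id,
                        function(s) length(unique(s)))
  birder_hotspots <- tapply(lists$hotspot, lists$birder,
                            function(h) length(unique(h)))
  out <- list(
    empty = FALSE,
    n_checklists = nrow(lists),
    n_birders = n_birders,
    n_visit_days = nrow(visits),
    n_hotspots = length(unique(lists$hotspot)),
    postings_per_birder = nrow(lists) / n_birders,
    species_per_list = mean(sp_per_list),
    visit_days_per_birder = nrow(visits) / n_birders,
    hotspots_per_birder = mean(birder_hotspots))
  class(out) <- "bud_descriptives"
  out
}

#' @export
print.bud_descriptives <- function(x, ...) {
  if (x$empty) {
    cat("Checklist descriptives: empty input\n")
    return(invisible(x))
  }
  cat("Checklist descriptives\n")
  cat(sprintf("  %d checklists by %d birders over %d visit days at %d hotspots\n",
              x$n_checklists, x$n_birders, x$n_visit_days, x$n_hotspots))
  cat(sprintf("  postings/birder %.2f, species/list %.2f, visit days/birder %.2f, hotspots/birder %.2f\n",
              x$postings_per_birder, x$species_per_list,
              x$visit_days_per_birder, x$hotspots_per_birder))
  invisible(x)
}

#' Build the monthly site panel from checklists
#'
#' Stacks one `MonthlySiteRecord` row per hotspot-month: BuD count, species
#' richness (all species and long-list subset) and calendar fields, over the
#' complete 1..T window for every hotspot.
#'
#' @inheritParams aggregate_buds
#' @param hotspots character vector of hotspot ids to include (defaults to
#'   those present in the data).
#' @param longlist optional freshwater-habitat species list.
#' @return data frame with columns `hotspot_id`, `month_index`,
#'   `month_of_year`, `bud_count`, `richness_all`, `richness_water`.
#' @export
build_panel <- function(checklists, epoch, n_months, hotspots = NULL,
                        longlist = NULL) {
  hotspots <- hotspots %||% sort(unique(checklists$hotspot_id))
  epoch_m <- as.integer(format(as.Date(epoch), "%m"))
  out <- vector("list", length(hotspots))
  for (i in seq_along(hotspots)) {
    h <- hotspots[i]
    buds <- aggregate_buds(checklists, h, epoch, n_months)
    rich <- monthly_richness(checklists, h, epoch, n_months, longlist)
    out[[i]] <- data.frame(
      hotspot_id = h, month_index = buds$month_index,
      month_of_year = month_of_year(buds$month_index, epoch_m),
      bud_count = buds$bud_count, richness_all = rich$richness_all,
      richness_water = rich$richness_water)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
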