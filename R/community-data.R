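## Community-data assembly: weekly-to-annual aggregation, prevalence
## filtering, wing-span binning and trait encoding.

#' Aggregate weekly trap samples to trap-year sums
#'
#' Sums weekly counts per (site, year, species) and counts operating days
#' as effort. Units and species present in the records but with zero total
#' are retained as zeros.
#'
#' @param weekly data.frame with columns `site`, `year`, `week`,
#'   `species`, `count`. Effort is `daysPerSample` times the number of
#'   distinct sampling weeks of the trap-year. `zone`, `lat`, `lon`
#'   columns, if present, are carried through per unit.
#' @param daysPerSample operating days per weekly sample (default 7).
#' @return a [CommunityTable-class].
#' @export
aggregateToTrapYear <- function(weekly, daysPerSample = 7) {
  need <- c("site", "year", "week", "species", "count")
  stopifnot(all(need %in% names(weekly)))
  if (any(weekly$count < 0)) stop("negative counts are not allowed")
  unitKey <- paste(weekly$site, weekly$year, sep = "_")
  ukeys <- unique(unitKey)
  ukeys <- ukeys[order(ukeys)]  # deterministic unit order
  species <- sort(unique(weekly$species))
  counts <- matrix(0, length(species), length(ukeys),
                   dimnames = list(species, ukeys))
  agg <- tapply(weekly$count,
                list(factor(weekly$species, species),
                     factor(unitKey, ukeys)), sum)
  agg[is.na(agg)] <- 0
  counts[] <- agg
  nweeks <- vapply(split(weekly$week, factor(unitKey, ukeys)),
                   function(w) length(unique(w)), integer(1))
  first <- match(ukeys, unitKey)
  meta <- data.frame(site = weekly$site[first], year = weekly$year[first],
                     effort_days = pmax(1, daysPerSample * nweeks),
                     stringsAsFactors = FALSE)
  for (extra in c("zone", "lat", "lon")) {
    if (extra %in% names(weekly)) meta[[extra]] <- weekly[[extra]][first]
  }
  if (is.null(meta$zone)) meta$zone <- "zone1"
  CommunityTable(counts, meta)
}

#' Filter species by prevalence across trap-years
#'
#' Retains species present (count > 0) in strictly more than `threshold`
#' of the trap-year units, and reports what fraction of all occurrence
#' records and of total abundance the retained species carry.
#'
#' @param table a [CommunityTable-class].
#' @param threshold prevalence threshold in `(0, 1)`; the default 0.10
#'   keeps species with prevalence above 10%. `threshold = 0` keeps every
#'   species observed at least once.
#' @return the filtered [CommunityTable-class]; the report is attached as
#'   `metadata(x)$prevalenceReport` with elements `kept`, `dropped`,
#'   `occurrenceFractionRetained`, `abundanceFractionRetained`.
#' @export
prevalenceFilter <- function(table, threshold = 0.10) {
  stopifnot(is(table, "CommunityTable"))
  if (ncol(table) == 0) stop("empty community table")
  stopifnot(threshold >= 0, threshold < 1)
  pa <- presenceAbsence(table)
  prev <- rowMeans(pa)
  keep <- if (threshold == 0) rowSums(pa) > 0 else prev > threshold
  cnt <- assay(table, "counts")
  report <- list(
    kept = rownames(table)[keep],
    dropped = rownames(table)[!keep],
    occurrenceFractionRetained = sum(pa[keep, ]) / max(1, sum(pa)),
    abundanceFractionRetained = sum(cnt[keep, ]) / max(1, sum(cnt))
  )
  out <- table[keep, ]
  metadata(out)$prevalenceReport <- report
  out
}

#' Wing-span bin edges
#'
#' The six ordinal wing-span groups: the singleton wingless group
#' (W = 0 mm), four interior intervals with edges at 17.9, 24.1, 30.3,
#' 36.5 and 43 mm, and a singleton top group for any span above the last
#' edge.
#' @return numeric vector of interior edges.
#' @export
wingBinEdges <- function() c(17.9, 24.1, 30.3, 36.5, 43)

#' Assign ordinal wing-span bins
#'
#' Bin 1 is the wingless group (`wing_span == 0`); bins 2-5 are the
#' interior intervals between the edges of [wingBinEdges()]; bin 6 is the
#' top group for spans above the last edge. A positive span below the
#' first edge (possible in synthetic data) is assigned to the nearest bin
#' with a warning.
#'
#' @param traits data.frame with columns `species` and `wing_span` (mm,
#'   `>= 0`).
#' @return `traits` with an added integer `wing_bin` column.
#' @export
#' @examples
#' assignWingBins(data.frame(species = "a", wing_span = 25))$wing_bin  # 3
assignWingBins <- function(traits) {
  stopifnot(all(c("species", "wing_span") %in% names(traits)),
            all(traits$wing_span >= 0))
  w <- traits$wing_span
  edges <- wingBinEdges()
  bin <- ifelse(w == 0, 1L, findInterval(w, edges) + 1L)
  low <- w > 0 & w <= edges[1]
  if (any(low)) {
    warning(sum(low), " wing span(s) below the first bin edge assigned ",
            "to the nearest bin")
    bin[low] <- 2L
  }
  bin[w > edges[length(edges)]] <- 6L
  traits$wing_bin <- as.integer(pmin(bin, 6L))
  traits
}

#' Host-plant group vocabulary
#' @return character vector of the six larval host-plant groups; the first
#'   entry (`herbaceous`) is the reference level of the trait encoding.
#' @export
hostGroups <- function() c("herbaceous", "graminoid", "dwarf_shrub",
                           "deciduous", "conifer", "other")

#' Encode species traits into the trait design matrix
#'
#' Columns: intercept, standardized continuous wing span, and five
#' host-group indicators with `herbaceous` as the reference level
#' (7 columns).
#'
#' @param traits data.frame with `species`, `wing_span`, `host_group`
#'   (values from [hostGroups()]).
#' @return numeric matrix, one row per species.
#' @export
encodeTraits <- function(traits) {
  stopifnot(all(c("species", "wing_span", "host_group") %in% names(traits)))
  bad <- setdiff(unique(traits$host_group), hostGroups())
  if (length(bad)) stop("unknown host group(s): ", paste(bad, collapse = ", "))
  w <- traits$wing_span
  wz <- if (sd(w) > 0) (w - mean(w)) / sd(w) else w * 0
  hg <- factor(traits$host_group, levels = hostGroups())
  ind <- outer(hg, hostGroups()[-1], "==") * 1
  colnames(ind) <- paste0("host_", hostGroups()[-1])
  Tm <- cbind(intercept = 1, wing_span = wz, ind)
  rownames(Tm) <- traits$species
  Tm
}
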