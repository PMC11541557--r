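#' Bleaching response categories
#'
#' The four colony response categories used by the bar-drop survey protocol,
#' in increasing order of severity, with their severity weights (0-3).
#' @return Named integer vector of weights.
#' @export
bleach_categories <- function() {
  c(normal = 0L, pale = 1L, partially_bleached = 2L, fully_bleached = 3L)
}

#' Bleaching severity index (BSI)
#'
#' Weighted proportion of affected colonies:
#' `scale * ((c2 + 2*c3 + 3*c4)/3) / n`, where c2/c3/c4 are the counts of
#' pale, partially bleached and fully bleached colonies and n the total number
#' of colonies surveyed. On the default 0-100 scale a reef where 28% of
#' colonies are fully bleached (and the rest normal) scores 28.0, so the index
#' reads as "percent of colonies affected, severity-weighted".
#'
#' @param n Total colonies (>= 1). Vectorized.
#' @param c2,c3,c4 Counts of pale, partially bleached, fully bleached.
#' @param scale Reporting scale: 100 (default) or 1 for the raw proportion.
#' @return BSI on `[0, scale]`.
#' @export
bleaching_severity <- function(n, c2, c3, c4, scale = 100) {
  if (any(n < 1)) stopf("n must be >= 1")
  if (any(c2 < 0 | c3 < 0 | c4 < 0)) stopf("category counts must be >= 0")
  if (any(c2 + c3 + c4 > n)) stopf("category counts exceed total colonies n")
  scale * ((c2 + 2 * c3 + 3 * c4) / 3) / n
}

# Category counts (n, c2, c3, c4) from a colony table with columns
# `category` and `count`.
.category_counts <- function(colonies) {
  cats <- names(bleach_categories())
  bad <- setdiff(unique(colonies$category), cats)
  if (length(bad)) stopf("unknown bleaching categories: %s",
                         paste(bad, collapse = ", "))
  tot <- vapply(cats, function(k) sum(colonies$count[colonies$category == k]), 0.0)
  c(n = sum(tot), c2 = tot[["pale"]], c3 = tot[["partially_bleached"]],
    c4 = tot[["fully_bleached"]])
}

#' BSI of one survey
#'
#' @param colonies `data.frame` with columns `species`, `category`, `count`
#'   for one reef-level observation.
#' @param scale Reporting scale, see [bleaching_severity].
#' @export
survey_bsi <- function(colonies, scale = 100) {
  k <- .category_counts(colonies)
  bleaching_severity(k[["n"]], k[["c2"]], k[["c3"]], k[["c4"]], scale = scale)
}

#' Species-level bleaching sensitivity table
#'
#' Pools colonies of each species across all surveys and evaluates the
#' bleaching severity index per species on the raw `[0, 1]` scale. Species
#' with fewer than `min_colonies` pooled colonies are excluded (their
#' species-level severity would be noisy) and reported in the
#' `excluded_species` attribute.
#'
#' @param surveys Tidy survey `data.frame` with columns `species`, `category`,
#'   `count` (site/date columns are ignored: pooling is across all rows).
#' @param min_colonies Minimum pooled colonies per species (default 50).
#' @return `data.frame` with columns `species`, `bsi_sp` (in `[0, 1]`) and
#'   `n_colonies`, ordered by decreasing `bsi_sp`; attribute
#'   `min_colonies` records the threshold.
#' @export
species_bsi_table <- function(surveys, min_colonies = 50) {
  if (nrow(surveys) == 0L) stopf("no survey rows supplied")
  sp <- split(surveys, surveys$species)
  tab <- do.call(rbind, lapply(names(sp), function(s) {
    k <- .category_counts(sp[[s]])
    data.frame(species = s,
               bsi_sp = bleaching_severity(k[["n"]], k[["c2"]], k[["c3"]],
                                           k[["c4"]], scale = 1),
               n_colonies = as.integer(k[["n"]]),
               stringsAsFactors = FALSE)
  }))
  drop <- tab$n_colonies < min_colonies
  out <- tab[!drop, , drop = FALSE]
  if (nrow(out) == 0L) stopf("no species reaches min_colonies = %d", min_colonies)
  out <- out[order(-out$bsi_sp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_colonies") <- min_colonies
  attr(out, "excluded_species") <- tab$species[drop]
  out
}

# Relative abundances (summing to 1) of species with an entry in `values`
# (a named numeric vector); colonies of unmatched species are dropped.
.matched_weights <- function(colonies, values, what) {
  counts <- tapply(colonies$count, colonies$species, sum)
  keep <- names(counts) %in% names(values)
  if (!any(keep)) stopf("no surveyed species has a %s value", what)
  counts <- counts[keep]
  list(w = as.numeric(counts) / sum(counts), species = names(counts))
}

#' Reef sensitivity index (SI_reef)
#'
#' Abundance-weighted mean of species-level bleaching severities: the
#' relative abundance of each species (percent of classifiable colonies,
#' divided by 100) times its species severity on `[0, 1]`, summed. Colonies
#' of species absent from the sensitivity table are excluded from both
#' numerator and denominator.
#'
#' @param colonies Colony table for one observation (columns `species`,
#'   `category`, `count`).
#' @param si_table A [species_bsi_table].
#' @return SI_reef in `[0, 1]` (a convex combination of the contributing
#'   species severities).
#' @export
si_reef <- function(colonies, si_table) {
  vals <- setNames(si_table$bsi_sp, si_table$species)
  m <- .matched_weights(colonies, vals, "bleaching sensitivity")
  sum(m$w * vals[m$species])
}

#' Reef functional index (RFI)
#'
#' Abundance-weighted mean of species functional coefficients (a
#' morphology/growth-based proxy for structural complexity). Species without
#' a coefficient fall back to a congener's value (same genus, first
#' alphabetically) when one exists; colonies of species with no assignable
#' coefficient are dropped from the calculation.
#'
#' @param colonies Colony table for one observation.
#' @param fc_table `data.frame` with columns `species` and `fc` (> 0).
#' @return List-free numeric RFI value; attribute `fallback` names species
#'   scored through a congener.
#' @export
rfi <- function(colonies, fc_table) {
  if (any(fc_table$fc <= 0)) stopf("functional coefficients must be > 0")
  fc <- setNames(fc_table$fc, fc_table$species)
  genus <- function(s) vapply(strsplit(s, "[ _]"), `[`, "", 1L)
  fc_genus <- genus(names(fc))
  need <- setdiff(unique(colonies$species), names(fc))
  fallback <- character(0)
  for (s in need) {
    hit <- which(fc_genus == genus(s))
    if (length(hit)) {
      donor <- sort(names(fc)[hit])[1]
      fc[s] <- fc[[donor]]
      fallback[s] <- donor
    }
  }
  m <- .matched_weights(colonies, fc, "functional coefficient")
  out <- sum(m$w * fc[m$species])
  attr(out, "fallback") <- fallback
  out
}

#' Hill's N1 diversity (effective species)
#'
#' Exponential of Shannon entropy over relative abundances: the number of
#' equally common species that would give the community's average species
#' rarity. Zero-count species are ignored.
#'
#' @param abundances Numeric vector of species counts or relative abundances.
#' @return Effective number of species in `[1, richness]`.
#' @export
hill_n1 <- function(abundances) {
  x <- abundances[abundances > 0]
  if (length(x) == 0L || sum(x) <= 0) stopf("no positive abundances")
  exp(vegan::diversity(x, index = "shannon"))
}

#' Species richness
#'
#' @param abundances Numeric vector of species counts.
#' @return Number of species with positive count (0 with a warning for an
#'   empty community).
#' @export
richness <- function(abundances) {
  r <- sum(abundances > 0)
  if (r == 0L) warnf("empty community: richness 0")
  as.integer(r)
}

#' First detrended-correspondence-analysis axis of a community matrix
#'
#' Places sites on the dominant compositional gradient: correspondence
#' analysis by reciprocal averaging with segment-wise detrending of the first
#' axis (26 segments by default, no nonlinear rescaling). The algebraic sign
#' of an ordination axis is arbitrary; scores are oriented so that they
#' correlate positively with the relative abundance of the overall most
#' abundant species, making pipelines reproducible.
#'
#' @param comm Sites x species matrix of (relative) abundances, with row and
#'   column names. All-zero rows/columns are dropped with a warning.
#' @param detrend Use detrending (default) or plain reciprocal-averaging
#'   correspondence analysis.
#' @param segments Number of detrending segments.
#' @return Named numeric vector of axis-1 site scores.
#' @export
dca_axis1 <- function(comm, detrend = TRUE, segments = 26) {
  comm <- as.matrix(comm)
  zr <- rowSums(comm) <= 0
  zc <- colSums(comm) <= 0
  if (any(zr) || any(zc)) {
    warnf("dropping %d all-zero rows and %d all-zero columns", sum(zr), sum(zc))
    comm <- comm[!zr, !zc, drop = FALSE]
  }
  if (nrow(comm) < 3L || ncol(comm) < 3L) {
    stopf("need at least 3 sites and 3 species (got %d x %d)",
          nrow(comm), ncol(comm))
  }
  if (qr(scale(comm, scale = FALSE))$rank < 2L) stopf("community matrix is degenerate (rank < 2)")
  ord <- vegan::decorana(comm, iweigh = 0, iresc = 0, mk = segments,
                         ira = if (detrend) 0 else 1)
  sc <- vegan::scores(ord, display = "sites", choices = 1)
  sc <- setNames(as.numeric(sc), rownames(comm))
  dom <- which.max(colSums(comm))
  relab <- comm[, dom] / rowSums(comm)
  r <- suppressWarnings(cor(sc, relab))
  if (is.finite(r) && r < 0) sc <- -sc
  sc
}

#' All field-based reef indices for one observation
#'
#' Bundles the six field-based metrics for one reef-level observation:
#' bleaching severity (0-100), reef sensitivity, functional index, species
#' richness, Hill N1 diversity and the ordination score.
#'
#' @param colonies Colony table for the observation (columns `species`,
#'   `category`, `count`).
#' @param si_table A [species_bsi_table].
#' @param fc_table Functional coefficient table, or `NULL` to skip RFI.
#' @param dca_score Precomputed axis-1 score for this observation (from
#'   [dca_axis1] on the full site x species matrix), or `NA`.
#' @param site_id,date,depth Observation metadata carried through.
#' @return One-row `data.frame`: `site_id`, `date`, `depth`, `bsi`,
#'   `si_reef`, `rfi`, `richness`, `diversity_n1`, `dca1`.
#' @export
reef_index_set <- function(colonies, si_table, fc_table = NULL,
                           dca_score = NA_real_, site_id = NA, date = NA,
                           depth = NA_real_) {
  ab <- tapply(colonies$count, colonies$species, sum)
  data.frame(
    site_id = site_id, date = date, depth = depth,
    bsi = survey_bsi(colonies),
    si_reef = si_reef(colonies, si_table),
    rfi = if (is.null(fc_table)) NA_real_ else as.numeric(rfi(colonies, fc_table)),
    richness = richness(ab),
    diversity_n1 = hill_n1(ab),
    dca1 = dca_score,
    stringsAsFactors = FALSE
  )
}
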