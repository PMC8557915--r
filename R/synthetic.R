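#' Default treatment archetypes
#'
#' Fifteen treatments spanning the qualitative structure of the
#' monoassociation panel: five acetic-acid-bacteria-like treatments (early
#' fecundity peak around days 12.5--14, higher late-life mortality), six
#' lactic-acid-bacteria-like treatments (late peak around days 18--21, low
#' mortality), single axenic, Bacillus-like, Enterobacteriales-like and
#' five-species-community-like treatments in between, and one pathogen-like
#' treatment with low fecundity and high mortality.  Peak daily fecundities
#' are calibrated so that vial fitness lambda lands around 2 per age class.
#'
#' @return list of \linkS4class{TreatmentArchetype}.
#' @export
defaultArchetypes <- function() {
  aab <- function(name, peak, amp)
    treatmentArchetype(name, peak, amp, shape = 6,
                       hazardBreaks = c(0, 24), hazardRates = c(0.006, 0.06))
  lab <- function(name, peak, amp)
    treatmentArchetype(name, peak, amp, shape = 5,
                       hazardBreaks = 0, hazardRates = 0.005)
  c(list(
    aab("A_pomorum_like", 12.5, 1.26),
    aab("A_tropicalis_like", 13, 1.19),
    aab("A_pasteurianus_like", 13.5, 1.12),
    aab("A_aceti_like", 14, 1.05),
    aab("A_malorum_like", 13, 1.16),
    lab("L_plantarum_like", 18, 0.91),
    lab("L_brevis_like", 19, 0.84),
    lab("L_fructivorans_like", 20, 0.77),
    lab("L_casei_like", 21, 0.81),
    lab("Lc_lactis_like", 20.5, 0.88),
    lab("L_rhamnosus_like", 19.5, 0.84),
    treatmentArchetype("B_subtilis_like", 16, 0.98, shape = 5,
                       hazardBreaks = 0, hazardRates = 0.012),
    treatmentArchetype("E_coli_like", 16.5, 1.02, shape = 5,
                       hazardBreaks = 0, hazardRates = 0.012),
    treatmentArchetype("five_species_like", 14.5, 1.12, shape = 5.5,
                       hazardBreaks = c(0, 24), hazardRates = c(0.008, 0.04)),
    treatmentArchetype("P_putida_like", 13, 0.42, shape = 5,
                       hazardBreaks = c(0, 10), hazardRates = c(0.01, 0.09),
                       pathogenLike = TRUE)))
}

#' Archetype rate functions
#'
#' \code{dailyFecundity} evaluates the gamma-kernel mean laying rate
#' \eqn{m(t) = A (t/p)^g e^{g(1 - t/p)}} (offspring per female per day) at
#' days \code{t}; \code{dailyHazard} evaluates the piecewise-constant daily
#' death probability.
#'
#' @param archetype a \linkS4class{TreatmentArchetype}.
#' @param t days since egg collection.
#' @return numeric, same length as \code{t}.
#' @export
dailyFecundity <- function(archetype, t) {
  p <- archetype@fecundityPeakDay
  g <- archetype@fecundityShape
  ifelse(t <= 0, 0,
         archetype@fecundityAmplitude * (t / p)^g * exp(g * (1 - t / p)))
}

#' @rdname dailyFecundity
#' @export
dailyHazard <- function(archetype, t) {
  idx <- findInterval(t, archetype@hazardBreaks)
  archetype@hazardRates[pmax(idx, 1L)]
}

.intervalGrid <- function(design) {
  len <- rep_len(design@intervalPatternDays, design@nIntervals)
  start <- design@firstTransferDay + cumsum(c(0, len[-design@nIntervals]))
  list(start = start, len = len)
}

#' Simulate one vial
#'
#' Emulates the measurement process of the vial assay for one treatment:
#' per interval, deaths are binomial with probability
#' \eqn{1 - (1 - h)^{days}} from the archetype's daily hazard, transfer
#' losses are binomial with the per-transfer loss probability, and the 18-h
#' pupae count is negative binomial with mean
#' \eqn{females \times m(t) \times window/24} evaluated at the middle of
#' the laying window.
#'
#' @param archetype a \linkS4class{TreatmentArchetype}.
#' @param nFemales starting female count.
#' @param design a \linkS4class{StudyDesign} supplying the interval layout,
#'   loss probability and count dispersion.
#' @param vialId,experimentDay,replicate labels for the record.
#' @param seed optional seed; when NULL the current RNG state is used.
#' @return a \linkS4class{VialRecord}.
#' @export
simulateVial <- function(archetype, nFemales, design = studyDesign(),
                         vialId = archetype@name, experimentDay = 1L,
                         replicate = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- .intervalGrid(design)
  n <- design@nIntervals
  alive <- as.integer(nFemales)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tMid <- grid$start[i] + design@layingWindowHours / 24 / 2
    mu <- alive * dailyFecundity(archetype, tMid) * design@layingWindowHours / 24
    pupae <- if (mu > 0) stats::rnbinom(1L, size = design@dispersion, mu = mu) else 0L
    h <- dailyHazard(archetype, grid$start[i])
    deaths <- if (alive > 0) stats::rbinom(1L, alive, 1 - (1 - h)^grid$len[i]) else 0L
    censored <- if (alive - deaths > 0)
      stats::rbinom(1L, alive - deaths, design@lossProb) else 0L
    rows[[i]] <- data.frame(start_day = grid$start[i],
                            class_length_days = grid$len[i],
                            laying_window_hours = design@layingWindowHours,
                            pupae_count = as.integer(pupae),
                            females_at_start = alive,
                            female_deaths = as.integer(deaths),
                            females_censored = as.integer(censored))
    alive <- alive - deaths - censored
  }
  VialRecord(vialId, archetype@name, experimentDay, replicate,
             do.call(rbind, rows))
}

#' Expected vital schedule of an archetype
#'
#' The noise-free schedule the simulator fluctuates around: per interval,
#' expected fecundity \eqn{f_i = m(t_i) \times days_i} (the 18-h window
#' count extrapolated back to the full class) and expected survival
#' \eqn{s_i = (1 - h_i)^{days_i}}, framed by the pre-adult and terminal
#' boundary classes.  Its Euler-Lotka root is the treatment's "truth"
#' fitness.
#'
#' @param archetype a \linkS4class{TreatmentArchetype}.
#' @param design a \linkS4class{StudyDesign}.
#' @return a \linkS4class{VitalSchedule}.
#' @export
expectedSchedule <- function(archetype, design = studyDesign()) {
  grid <- .intervalGrid(design)
  tMid <- grid$start + design@layingWindowHours / 24 / 2
  f <- dailyFecundity(archetype, tMid) * grid$len
  s <- (1 - dailyHazard(archetype, grid$start))^grid$len
  VitalSchedule(c(0, f, 0), c(1, s))
}

#' Simulate a complete vial study
#'
#' Generates \code{nExperiments x vialsPerExperiment} vials per treatment
#' with starting female counts drawn uniformly from the design's range, a
#' weekly contamination log (optionally with injected contamination events
#' for filter testing), and the per-treatment truth fitness from
#' [expectedSchedule()].  Fully reproducible from the design's seed.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param nContaminated number of vials (taken from the start of the vial
#'   list) given an above-threshold unexpected-morphology signal in two
#'   consecutive weeks.
#' @return list with \code{vials} (a \linkS4class{VialRecordList}),
#'   \code{contamination} (data.frame log) and \code{truth} (data.frame
#'   with \code{treatment}, \code{lambda_truth}, \code{pathogen_like}).
#' @export
simulateStudy <- function(design = studyDesign(), nContaminated = 0L) {
  set.seed(design@seed)
  vials <- list()
  for (arch in design@treatments) {
    for (e in seq_len(design@nExperiments)) {
      for (r in seq_len(design@vialsPerExperiment)) {
        nF <- sample(seq(design@fliesPerVial[1L], design@fliesPerVial[2L]), 1L)
        id <- sprintf("%s_e%d_r%d", arch@name, e, r)
        vials[[id]] <- simulateVial(arch, nF, design, vialId = id,
                                    experimentDay = e, replicate = r)
      }
    }
  }
  vials <- VialRecordList(vials)
  ids <- names(vials)
  contaminated <- ids[seq_len(min(nContaminated, length(ids)))]
  logs <- do.call(rbind, lapply(ids, function(id) {
    hot <- id %in% contaminated
    cfu <- round(stats::runif(4, 0, 50))
    unexpected <- rep(FALSE, 4)
    if (hot) {
      cfu[2:3] <- round(stats::runif(2, 250, 450))
      unexpected[2:3] <- TRUE
    }
    data.frame(vial_id = id, week = 1:4, cfu_per_fly = cfu,
               unexpected_morphology = unexpected)
  }))
  truth <- data.frame(
    treatment = vapply(design@treatments, function(a) a@name, character(1)),
    lambda_truth = vapply(design@treatments, function(a)
      eulerLotkaLambda(expectedSchedule(a, design)), numeric(1)),
    pathogen_like = vapply(design@treatments, function(a) a@pathogenLike,
                           logical(1)))
  list(vials = vials, contamination = logs, truth = truth)
}

#' Simulate an OG presence/absence matrix with one planted PDG
#'
#' Background OGs receive i.i.d. Bernoulli(\code{q}) presence patterns
#' (duplicate patterns are expected and produce multi-OG PDGs).  One
#' additional OG carries the planted pattern; in the companion fitness
#' panel, strains matching that pattern receive a \code{+effectDelta} shift
#' to mean fitness.
#'
#' @param nOGs number of background OGs.
#' @param strainIds strain names (columns).
#' @param plantedPattern 0/1 vector over strains (must contain both 0s and
#'   1s); default splits the strains roughly in half.
#' @param effectDelta fitness shift carried by strains with the planted
#'   pattern.
#' @param q background presence probability.
#' @param seed optional seed.
#' @return list with \code{og} (an \linkS4class{OGMatrix} including the
#'   planted OG \code{"OG_planted"}), \code{shift} (named per-strain fitness
#'   shift) and \code{plantedPattern}.
#' @export
simulateOGMatrix <- function(nOGs, strainIds, plantedPattern = NULL,
                             effectDelta = 0.3, q = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- length(strainIds)
  if (is.null(plantedPattern))
    plantedPattern <- rep(c(1, 0), c(ceiling(ns / 2), floor(ns / 2)))
  plantedPattern <- as.numeric(plantedPattern)
  if (length(plantedPattern) != ns)
    stop("'plantedPattern' must have one entry per strain")
  if (all(plantedPattern == 0) || all(plantedPattern == 1))
    stop("'plantedPattern' must be non-degenerate")
  m <- matrix(stats::rbinom(nOGs * ns, 1L, q), nrow = nOGs,
              dimnames = list(sprintf("OG%04d", seq_len(nOGs)), strainIds))
  m <- rbind(m, OG_planted = plantedPattern)
  list(og = OGMatrix(m),
       shift = stats::setNames(effectDelta * plantedPattern, strainIds),
       plantedPattern = paste0(plantedPattern, collapse = ""))
}

#' Simulate a per-vial fitness panel for association testing
#'
#' Per-vial fitness values for a panel of strains, with Gaussian strain,
#' experiment (replicate) and residual components around a common baseline,
#' plus an optional per-strain shift (e.g. a planted PDG effect).  The
#' default variance components are calibrated to the spread of treatment
#' mean fitness seen in monoassociation panels (means near 2, strain means
#' ranging roughly 1.8--2.1).
#'
#' @param strainIds strain names.
#' @param shift named per-strain additive effect (default 0).
#' @param nExperiments,vialsPerExperiment panel layout (default 3 x 3).
#' @param baseline grand mean fitness.
#' @param strainSD,expSD,residSD standard deviations of the strain,
#'   experiment and residual components.
#' @param seed optional seed.
#' @return data.frame with \code{vial_id}, \code{strain_id},
#'   \code{experiment}, \code{lambda}.
#' @export
simulateFitnessPanel <- function(strainIds, shift = 0, nExperiments = 3L,
                                 vialsPerExperiment = 3L, baseline = 2,
                                 strainSD = 0.08, expSD = 0.05,
                                 residSD = 0.12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(shift) == 1L && is.null(names(shift)))
    shift <- stats::setNames(rep(shift, length(strainIds)), strainIds)
  strainEff <- stats::rnorm(length(strainIds), 0, strainSD)
  names(strainEff) <- strainIds
  expEff <- stats::rnorm(nExperiments, 0, expSD)
  rows <- expand.grid(replicate = seq_len(vialsPerExperiment),
                      experiment = seq_len(nExperiments),
                      strain_id = strainIds, stringsAsFactors = FALSE)
  rows$lambda <- baseline + strainEff[rows$strain_id] +
    shift[rows$strain_id] + expEff[rows$experiment] +
    stats::rnorm(nrow(rows), 0, residSD)
  data.frame(
    vial_id = sprintf("%s_e%d_r%d", rows$strain_id, rows$experiment,
                      rows$replicate),
    strain_id = rows$strain_id,
    experiment = rows$experiment,
    lambda = as.numeric(rows$lambda))
}
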