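#' Construct regime parameters
#'
#' Low-level constructor; most analyses start from \code{\link{regimePreset}}
#' and override fields as needed.
#'
#' @param name regime label.
#' @param meanCycleTime,preCycleTime,cycleCV,f,preF,regen,preRegen see
#'   \code{\link{RegimeParams-class}}.
#' @param storageCap,criticalSize,sizeGrowthRate see class docs; the growth
#'   rate defaults to one critical size per 30 min (rapid G1 growth).
#' @param daughterSizeFraction,preDaughterSizeFraction,shiftTime see class
#'   docs.
#' @param slowdownRef,slowdownGamma resource-to-cycle-time coupling: cycle
#'   times are multiplied by \code{max(1, slowdownRef/resource)^slowdownGamma}.
#' @param resourceParams a \code{\link{ResourceParams}}.
#' @return a validated \code{RegimeParams}.
#' @export
regimeParams <- function(name, meanCycleTime, preCycleTime = meanCycleTime,
                         cycleCV = 0.15, f = 0.5, preF = 0.5,
                         regen = 0, preRegen = regen,
                         storageCap = resourceParams@z0,
                         criticalSize = 1,
                         sizeGrowthRate = criticalSize / 30,
                         daughterSizeFraction = 0.5,
                         preDaughterSizeFraction = 0.5,
                         shiftTime = 0,
                         slowdownRef = resourceParams@zc,
                         slowdownGamma = 1,
                         resourceParams = asymdiv::resourceParams(9, 1, 1)) {
  new("RegimeParams", name = name,
      meanCycleTime = as.numeric(meanCycleTime),
      preCycleTime = as.numeric(preCycleTime), cycleCV = as.numeric(cycleCV),
      f = as.numeric(f), preF = as.numeric(preF),
      regen = as.numeric(regen), preRegen = as.numeric(preRegen),
      storageCap = as.numeric(storageCap),
      criticalSize = as.numeric(criticalSize),
      sizeGrowthRate = as.numeric(sizeGrowthRate),
      daughterSizeFraction = as.numeric(daughterSizeFraction),
      preDaughterSizeFraction = as.numeric(preDaughterSizeFraction),
      shiftTime = as.numeric(shiftTime),
      slowdownRef = as.numeric(slowdownRef),
      slowdownGamma = as.numeric(slowdownGamma),
      resourceParams = resourceParams)
}

#' Regime presets for the studied growth conditions
#'
#' Returns ready-made \code{\link{RegimeParams}} encoding the experimental
#' conditions studied in the package:
#' \describe{
#'   \item{rich}{non-limiting medium; symmetric vacuole partitioning,
#'     fast replenishment, 103 min mean cycle time, exponential growth.}
#'   \item{low_metal}{direct shift from rich to low zinc at 3 h; mothers
#'     retain the vacuolar pool (f = 0.98), no replenishment, 120 min
#'     cycles, a pool sized for 8 post-shift divisions per progenitor,
#'     daughters born 35\% smaller and arresting.}
#'   \item{preadapted}{low zinc after pre-adaptation in an intermediate
#'     zinc concentration; 150 min cycles and a smaller spare pool
#'     (4\enc{–}{-}5 divisions).}
#'   \item{semi_low}{intermediate zinc at which wild type still grows
#'     exponentially, with slower (150 min) cycles.}
#'   \item{whi5}{WHI5 deletion in low zinc: the Start size threshold is
#'     reduced by 30\%, the vacuole is split evenly so all cells divide,
#'     and cycle times lengthen as the pool dilutes (slowdown referenced
#'     to the initial pool).}
#'   \item{whi5_rich}{WHI5 deletion in rich medium: normal growth rate,
#'     cells 30\% smaller than wild type.}
#'   \item{vac17}{VAC17 deletion in semi-low zinc: vacuole transport to
#'     the bud is blocked (f = 1) and regeneration is impaired, so growth
#'     is linear with 180 min cycles from the outset.}
#'   \item{zrc1cot1}{ZRC1 COT1 double deletion: a reduced vacuolar zinc
#'     store (smaller Z0) brings the transition to mother-only division
#'     earlier, with slowed (150 min) mother cycles.}
#' }
#'
#' Any field can be overridden through \code{...}, e.g.
#' \code{regimePreset("low_metal", cycleCV = 0)}.
#'
#' @param name preset name.
#' @param ... named \code{\link{regimeParams}} arguments overriding the
#'   preset's defaults.
#' @return a \code{RegimeParams}.
#' @examples
#' regimePreset("low_metal")
#' regimePreset("rich", cycleCV = 0)
#' @export
regimePreset <- function(name = c("rich", "low_metal", "preadapted",
                                  "semi_low", "whi5", "whi5_rich",
                                  "vac17", "zrc1cot1"), ...) {
  name <- match.arg(name)
  rp9 <- resourceParams(9, 1, 1)
  args <- switch(name,
    rich = list(meanCycleTime = 103, f = 0.5, regen = 0.5,
                daughterSizeFraction = 0.5, shiftTime = 0,
                resourceParams = rp9),
    low_metal = list(meanCycleTime = 120, preCycleTime = 103,
                     f = 0.98, preF = 0.5, regen = 0, preRegen = 0.5,
                     daughterSizeFraction = 0.65,
                     preDaughterSizeFraction = 0.5, shiftTime = 180,
                     resourceParams = resourceParams(10, 1, 1)),
    preadapted = list(meanCycleTime = 150, preCycleTime = 103,
                      f = 0.98, preF = 0.5, regen = 0, preRegen = 0.5,
                      daughterSizeFraction = 0.65,
                      preDaughterSizeFraction = 0.5, shiftTime = 180,
                      resourceParams = resourceParams(6.5, 1, 1)),
    semi_low = list(meanCycleTime = 150, f = 0.5, regen = 0.2,
                    daughterSizeFraction = 0.5, shiftTime = 0,
                    resourceParams = rp9),
    whi5 = list(meanCycleTime = 120, preCycleTime = 103,
                f = 0.5, preF = 0.5, regen = 0, preRegen = 0.5,
                daughterSizeFraction = 0.5,
                preDaughterSizeFraction = 0.5, shiftTime = 180,
                criticalSize = 0.7, slowdownRef = 9,
                resourceParams = rp9),
    whi5_rich = list(meanCycleTime = 103, f = 0.5, regen = 0.5,
                     daughterSizeFraction = 0.5, shiftTime = 0,
                     criticalSize = 0.7, resourceParams = rp9),
    vac17 = list(meanCycleTime = 180, f = 1, preF = 1, regen = 0,
                 daughterSizeFraction = 0.65,
                 preDaughterSizeFraction = 0.65, shiftTime = 0,
                 resourceParams = rp9),
    zrc1cot1 = list(meanCycleTime = 150, preCycleTime = 103,
                    f = 0.98, preF = 0.5, regen = 0, preRegen = 0.5,
                    daughterSizeFraction = 0.65,
                    preDaughterSizeFraction = 0.5, shiftTime = 180,
                    resourceParams = resourceParams(5, 1, 1)))
  over <- list(...)
  args[names(over)] <- over
  do.call(regimeParams, c(list(name = name), args))
}
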