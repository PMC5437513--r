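#' @useDynLib ferrokin, .registration = TRUE
#' @importFrom stats sd setNames approx optimize rnorm runif t.test p.adjust
#' @importFrom utils read.csv write.csv modifyList head tail
NULL

#' Molar mass of iron (g/mol)
#' @keywords internal
FE_MOLAR_MASS <- 55.845

# Compartment volumes (litres), from organ masses and densities of the
# seven body compartments; "outside" carries no volume.
.default_volumes <- c(
  bone_marrow = 2.1e-4,
  duodenum    = 3.9e-5,
  liver       = 1.2e-3,
  plasma      = 1.3e-3,
  rbc         = 7.9e-4,
  rest        = 2.0e-2,
  spleen      = 6.7e-5
)

#' Compartment table of the whole-body iron model
#'
#' The seven body compartments with their volumes in litres, plus the
#' volume-less `outside` compartment that accumulates excreted iron.
#'
#' @param volumes named numeric vector overriding any of the seven default
#'   body-compartment volumes (litres).
#' @return data.frame with columns `name` and `volume` (NA for `outside`).
#' @export
iron_compartments <- function(volumes = NULL) {
  v <- .default_volumes
  if (!is.null(volumes)) {
    bad <- setdiff(names(volumes), names(v))
    if (length(bad)) stop("unknown compartment(s): ", paste(bad, collapse = ", "))
    if (any(volumes <= 0)) stop("compartment volumes must be positive")
    v[names(volumes)] <- volumes
  }
  data.frame(name = c(names(v), "outside"),
             volume = c(unname(v), NA_real_),
             stringsAsFactors = FALSE)
}

.param_names <- c(
  "kInDuo", "kInLiver", "kInRBC", "kInRest", "kInBM",
  "kDuoLoss", "kRestOut", "kBMSpleen", "vRBCSpleen",
  "VDuoNTBI", "VLiverNTBI", "VSpleenNTBI", "VRestNTBI",
  "Km", "Ki", "vDiet", "kNTBI_Fe1Tf", "kFe1Tf_Fe2Tf",
  "kHepSyn", "kHepDeg", "TfTotal"
)

#' Construct a validated parameter set
#'
#' Holds all kinetic constants of the model: first-order rate constants
#' (per day) for transferrin-mediated import, erythroid cycling and iron
#' loss; ferroportin limiting rates (molar/day — multiplied by the source
#' compartment volume to give mol/day); the shared ferroportin `Km` and the
#' hepcidin non-competitive constant `Ki` (molar); the dietary influx
#' `vDiet` (molar/day, applied over the duodenum volume); transferrin
#' binding constants (per molar per day); hepcidin synthesis (molar/day)
#' and degradation (per day); and the conserved total transferrin
#' concentration `TfTotal` (molar).
#'
#' Hepcidin submodel defaults give a circulating level of 23 nM
#' (`kHepSyn`/`kHepDeg` with `kHepDeg` = 1/day).  `Ki` defaults to
#' 0.973 nM, the value at which the canonical adequate-diet rate
#' constants reproduce their own published steady state (total body iron
#' 2.20 mg, transferrin saturation ~47%, NTBI ~33 nM): a much weaker
#' inhibition (`Ki` near the circulating 23 nM level) leaves ferroportin
#' export essentially uninhibited and the system has no physiological
#' steady state.  All three hepcidin constants are exposed precisely
#' because they are weakly determined by tracer data alone.
#'
#' @param ... named parameter values overriding the defaults.
#' @param base optional existing `iron_params` to start from.
#' @return named numeric vector of class `iron_params`.
#' @examples
#' p <- iron_params(vRBCSpleen = 0.0235)
#' 1 / p[["vRBCSpleen"]]  # RBC transition time, days
#' @export
iron_params <- function(..., base = NULL) {
  defaults <- c(published_params(6, raw = TRUE),
                Ki = 9.73e-10, kHepSyn = 23e-9, kHepDeg = 1.0, TfTotal = 3.87e-5)
  if (!is.null(base)) {
    stopifnot(inherits(base, "iron_params"))
    defaults[names(base)] <- base
  }
  over <- c(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("all parameter overrides must be named")
    bad <- setdiff(names(over), .param_names)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    defaults[names(over)] <- over
  }
  p <- defaults[.param_names]
  names(p) <- .param_names
  if (anyNA(p)) stop("missing parameter(s): ",
                     paste(.param_names[is.na(p)], collapse = ", "))
  strict <- setdiff(.param_names, "vDiet")  # zero influx = starvation, legal
  if (any(p[strict] <= 0) || p[["vDiet"]] < 0)
    stop("all parameters must be strictly positive (vDiet >= 0); offending: ",
         paste(names(p)[p < 0 | (names(p) != "vDiet" & p == 0)],
               collapse = ", "))
  structure(p, class = "iron_params")
}

#' @export
print.iron_params <- function(x, ...) {
  cat("<iron_params> (", length(x), " constants; M, L, day units)\n", sep = "")
  print(format(unclass(x), digits = 4, scientific = TRUE), quote = FALSE)
  invisible(x)
}

# The ten independently estimated parameter sets for the adequate-diet
# calibration, columns #1..#10.  Column 6 is the canonical set (RBC
# transition time 42.5 d, Tf saturation 47%).
.published_sets <- local({
  m <- rbind(
    kInDuo       = c(0.236, 0.251, 0.322, 0.131, 0.250, 0.0690, 0.158, 0.134, 0.0381, 0.0347),
    kInLiver     = c(9.40, 9.99, 12.7, 5.35, 10.3, 2.98, 6.83, 5.72, 1.69, 1.55),
    kInRBC       = c(1.09, 1.09, 1.10, 1.09, 1.08, 1.08, 1.04, 1.07, 1.19, 1.20),
    kInRest      = c(18.3, 19.4, 24.7, 10.4, 22.0, 6.16, 13.9, 11.3, 3.20, 2.95),
    kInBM        = c(49.5, 52.7, 67.1, 28.1, 58.8, 15.8, 35.3, 29.7, 9.07, 8.26),
    kDuoLoss     = c(5.00e-4, 5.45e-4, 5.05e-4, 9.29e-4, 0.00359, 0.0270, 0.0313, 9.38e-4, 0.00150, 0.00150),
    kRestOut     = c(0.0238, 0.0239, 0.0239, 0.0238, 0.0234, 0.0236, 0.0234, 0.0236, 0.0236, 0.0234),
    kBMSpleen    = c(0.173, 0.173, 0.183, 0.143, 0.0453, 0.0619, 0.0680, 0.0900, 0.0585, 0.0567),
    VDuoNTBI     = c(2.03, 11.4, 3.56, 0.792, 0.910, 0.200, 0.200, 0.901, 0.0978, 0.566),
    VLiverNTBI   = c(0.551, 3.15, 0.982, 0.203, 0.0946, 0.0261, 0.0295, 0.204, 0.00847, 0.0937),
    VSpleenNTBI  = c(35.5, 202, 63.9, 12.6, 4.86, 1.34, 21.49, 10.9, 0.434, 3.89),
    VRestNTBI    = c(0.350, 2.01, 0.634, 0.121, 0.0212, 0.0109, 0.0128, 0.102, 0.00119, 0.0114),
    vRBCSpleen   = c(0.0833, 0.0831, 0.0870, 0.0706, 0.0132, 0.0235, 0.0283, 0.043, 0.0209, 0.0190),
    Km           = c(0.239, 1.38, 0.412, 0.100, 0.128, 0.0159, 0.0145, 0.119, 0.00850, 0.117),
    vDiet        = c(0.0042, 0.0042, 0.0042, 0.0042, 0.00318, 0.00377, 0.00397, 0.0042, 0.0042, 0.0042),
    kNTBI_Fe1Tf  = c(5e7, 5e7, 5e7, 5e7, 4.98e6, 1.08e9, 5.25e8, 5e7, 5e7, 5e7),
    kFe1Tf_Fe2Tf = c(5e7, 5e7, 5e7, 5e7, 10.1, 1.08e9, 5.25e8, 5e7, 5e7, 5e7)
  )
  colnames(m) <- paste0("#", 1:10)
  m
})

#' Published parameter estimates (ensemble of ten fits)
#'
#' Returns one column of the published ensemble of ten independent
#' adequate-diet parameter estimates, completed with the hepcidin submodel
#' defaults (`Ki`, `kHepSyn`, `kHepDeg`) and `TfTotal` which are not part
#' of the estimated table.
#'
#' @param column integer in 1..10; column 6 is the canonical model.
#' @param raw if TRUE, return only the 17 tabulated constants as a bare
#'   numeric vector (internal use).
#' @return `iron_params` (or bare vector when `raw = TRUE`).
#' @examples
#' published_params(6)[["vRBCSpleen"]]  # 0.0235 /day
#' @export
published_params <- function(column = 6, raw = FALSE) {
  if (!is.numeric(column) || length(column) != 1 || is.na(column) ||
      column < 1 || column > 10 || column != round(column))
    stop("column must be an integer in 1..10")
  v <- .published_sets[, column]
  if (raw) return(v)
  p <- c(v, Ki = 9.73e-10, kHepSyn = 23e-9, kHepDeg = 1.0, TfTotal = 3.87e-5)
  structure(p[.param_names], class = "iron_params",
            names = .param_names)
}

#' @rdname published_params
#' @export
published_ensemble <- function() .published_sets

#' Read / write a parameter set as flat JSON
#'
#' The on-disk schema is a flat JSON object keyed by the parameter names of
#' [iron_params()] (units: M, L, day, as documented there).
#'
#' @param path file path.
#' @return `read_params_json` returns an `iron_params`.
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(x) && !is.numeric(x)) stop("malformed parameter JSON")
  do.call(iron_params, as.list(unlist(x)))
}

#' @rdname read_params_json
#' @param params an `iron_params` object.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "iron_params"))
  jsonlite::write_json(as.list(unclass(params)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
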