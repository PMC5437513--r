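#' Assemble the whole-body iron distribution model
#'
#' Builds the full reaction network: constant dietary influx into the
#' duodenum; saturable, hepcidin-inhibited ferroportin export from
#' duodenum, liver, spleen and rest-of-body into plasma NTBI; irreversible
#' transferrin loading (NTBI + Tf -> Fe1Tf, NTBI + Fe1Tf -> Fe2Tf, all
#' label combinations); first-order transferrin-mediated iron delivery to
#' bone marrow, liver, duodenum and rest (apo-Tf returned to plasma,
#' di-ferric Tf delivering two iron ions); erythroid cycling (bone marrow
#' -> RBC, bone marrow -> spleen, RBC -> spleen); iron loss from duodenum
#' and rest to the volume-less `outside` pool; and constant hepcidin
#' synthesis with first-order degradation.
#'
#' With `include_tracer = TRUE` every iron reaction is mirrored for the
#' radioactive species (marked `*`), sharing its rate constant with the
#' unlabeled twin (kinetic isotope effects ignored), with competitive
#' coupling at the ferroportin transporter and the full six-way set of
#' transferrin binding combinations.  There is no direct iron acquisition
#' from plasma by the RBC pool: all RBC iron arrives via the bone marrow.
#' Hepcidin has no tracer twin and no feedback from the iron state.
#'
#' @param params an [iron_params()] set (or named vector with the same
#'   names; a missing binding is a configuration error naming it).
#' @param include_tracer logical; duplicate all iron reactions for the
#'   labeled species set.
#' @param volumes optional named override of compartment volumes (litres).
#' @return object of class `iron_model`: compartments, species table,
#'   reaction list, and the parameter set.
#' @examples
#' m <- build_model(published_params(6))
#' m
#' @export
build_model <- function(params, include_tracer = TRUE, volumes = NULL) {
  if (!inherits(params, "iron_params")) {
    if (is.null(names(params))) stop("params must be a named vector or iron_params")
    missing <- setdiff(.param_names, names(params))
    if (length(missing))
      stop("configuration error: missing parameter binding(s): ",
           paste(missing, collapse = ", "))
    params <- do.call(iron_params, as.list(params[.param_names]))
  }
  comp <- iron_compartments(volumes)

  sp <- .species_table(include_tracer)
  rx <- .reaction_list(include_tracer)

  # every rate-law parameter binding must resolve
  bound <- unique(unlist(lapply(rx, function(r) r$par)))
  missing <- setdiff(bound, names(params))
  if (length(missing))
    stop("configuration error: missing parameter binding(s): ",
         paste(missing, collapse = ", "))

  structure(list(params = params, compartments = comp, species = sp,
                 reactions = rx, include_tracer = include_tracer),
            class = "iron_model")
}

# species table: name, compartment, unit (conc/amount), iron content split
# into unlabeled (fe_u) and labeled (fe_l) ions carried per molecule
.species_table <- function(include_tracer) {
  if (include_tracer) {
    data.frame(
      name = c("FeBM", "FeBM*", "FeDuo", "FeDuo*", "FeLiver", "FeLiver*",
               "FeSpleen", "FeSpleen*", "FeRBC", "FeRBC*", "FeRest", "FeRest*",
               "FeOutside", "FeOutside*", "NTBI", "NTBI*", "Tf",
               "Fe1Tf", "Fe1Tf*", "Fe2Tf", "Fe2Tf*", "Fe2Tf**", "Hepcidin"),
      compartment = c(rep(c("bone_marrow", "duodenum", "liver", "spleen",
                            "rbc", "rest", "outside"), each = 2),
                      rep("plasma", 9)),
      unit = c(rep("conc", 12), "amount", "amount", rep("conc", 9)),
      fe_u = c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 0, 1, 0, 2, 1, 0, 0),
      fe_l = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 0, 1, 0, 1, 2, 0),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      name = c("FeBM", "FeDuo", "FeLiver", "FeSpleen", "FeRBC", "FeRest",
               "FeOutside", "NTBI", "Tf", "Fe1Tf", "Fe2Tf", "Hepcidin"),
      compartment = c("bone_marrow", "duodenum", "liver", "spleen", "rbc",
                      "rest", "outside", rep("plasma", 5)),
      unit = c(rep("conc", 6), "amount", rep("conc", 5)),
      fe_u = c(1, 1, 1, 1, 1, 1, 1, 1, 0, 1, 2, 0),
      fe_l = 0,
      stringsAsFactors = FALSE
    )
  }
}

.rxn <- function(name, kind, reactants, products, par, comp,
                 substrate = NULL, competitor = NULL) {
  list(name = name, kind = kind, reactants = reactants, products = products,
       par = par, comp = comp, substrate = substrate, competitor = competitor)
}

.reaction_list <- function(include_tracer) {
  rx <- list()
  add <- function(...) rx[[length(rx) + 1]] <<- .rxn(...)

  fpn_organs <- list(
    c(org = "Duo", sp = "FeDuo", comp = "duodenum", V = "VDuoNTBI"),
    c(org = "Liver", sp = "FeLiver", comp = "liver", V = "VLiverNTBI"),
    c(org = "Spleen", sp = "FeSpleen", comp = "spleen", V = "VSpleenNTBI"),
    c(org = "Rest", sp = "FeRest", comp = "rest", V = "VRestNTBI")
  )
  imp_organs <- list(
    c(org = "BM", sp = "FeBM", k = "kInBM"),
    c(org = "Liver", sp = "FeLiver", k = "kInLiver"),
    c(org = "Duo", sp = "FeDuo", k = "kInDuo"),
    c(org = "Rest", sp = "FeRest", k = "kInRest")
  )

  add("diet_influx", "constant", c(), c(FeDuo = 1), "vDiet", "duodenum")

  for (o in fpn_organs) {
    add(paste0("fpn_", o[["org"]]), "ferroportin",
        setNames(1, o[["sp"]]), c(NTBI = 1), o[["V"]], o[["comp"]],
        substrate = o[["sp"]],
        competitor = if (include_tracer) paste0(o[["sp"]], "*") else NULL)
    if (include_tracer)
      add(paste0("fpn_", o[["org"]], "_t"), "ferroportin",
          setNames(1, paste0(o[["sp"]], "*")), c(`NTBI*` = 1), o[["V"]],
          o[["comp"]], substrate = paste0(o[["sp"]], "*"),
          competitor = o[["sp"]])
  }

  add("bind_NTBI_Tf", "bimolecular", c(NTBI = 1, Tf = 1), c(Fe1Tf = 1),
      "kNTBI_Fe1Tf", "plasma")
  add("bind_NTBI_Fe1Tf", "bimolecular", c(NTBI = 1, Fe1Tf = 1), c(Fe2Tf = 1),
      "kFe1Tf_Fe2Tf", "plasma")
  if (include_tracer) {
    add("bind_NTBIt_Tf", "bimolecular", c(`NTBI*` = 1, Tf = 1),
        c(`Fe1Tf*` = 1), "kNTBI_Fe1Tf", "plasma")
    add("bind_NTBI_Fe1Tft", "bimolecular", c(NTBI = 1, `Fe1Tf*` = 1),
        c(`Fe2Tf*` = 1), "kFe1Tf_Fe2Tf", "plasma")
    add("bind_NTBIt_Fe1Tf", "bimolecular", c(`NTBI*` = 1, Fe1Tf = 1),
        c(`Fe2Tf*` = 1), "kFe1Tf_Fe2Tf", "plasma")
    add("bind_NTBIt_Fe1Tft", "bimolecular", c(`NTBI*` = 1, `Fe1Tf*` = 1),
        c(`Fe2Tf**` = 1), "kFe1Tf_Fe2Tf", "plasma")
  }

  for (o in imp_organs) {
    fe <- o[["sp"]]; fet <- paste0(fe, "*"); k <- o[["k"]]
    add(paste0("imp_Fe1Tf_", o[["org"]]), "mass_action",
        c(Fe1Tf = 1), setNames(c(1, 1), c("Tf", fe)), k, "plasma",
        substrate = "Fe1Tf")
    add(paste0("imp_Fe2Tf_", o[["org"]]), "mass_action",
        c(Fe2Tf = 1), setNames(c(1, 2), c("Tf", fe)), k, "plasma",
        substrate = "Fe2Tf")
    if (include_tracer) {
      add(paste0("imp_Fe1Tft_", o[["org"]]), "mass_action",
          c(`Fe1Tf*` = 1), setNames(c(1, 1), c("Tf", fet)), k, "plasma",
          substrate = "Fe1Tf*")
      add(paste0("imp_Fe2Tft_", o[["org"]]), "mass_action",
          c(`Fe2Tf*` = 1), setNames(c(1, 1, 1), c("Tf", fe, fet)), k,
          "plasma", substrate = "Fe2Tf*")
      add(paste0("imp_Fe2Tftt_", o[["org"]]), "mass_action",
          c(`Fe2Tf**` = 1), setNames(c(1, 2), c("Tf", fet)), k, "plasma",
          substrate = "Fe2Tf**")
    }
  }

  ery <- list(
    c(n = "bm_to_rbc", from = "FeBM", to = "FeRBC", k = "kInRBC", comp = "bone_marrow"),
    c(n = "bm_to_spleen", from = "FeBM", to = "FeSpleen", k = "kBMSpleen", comp = "bone_marrow"),
    c(n = "rbc_to_spleen", from = "FeRBC", to = "FeSpleen", k = "vRBCSpleen", comp = "rbc"),
    c(n = "duo_loss", from = "FeDuo", to = "FeOutside", k = "kDuoLoss", comp = "duodenum"),
    c(n = "rest_loss", from = "FeRest", to = "FeOutside", k = "kRestOut", comp = "rest")
  )
  for (e in ery) {
    add(e[["n"]], "mass_action", setNames(1, e[["from"]]),
        setNames(1, e[["to"]]), e[["k"]], e[["comp"]], substrate = e[["from"]])
    if (include_tracer)
      add(paste0(e[["n"]], "_t"), "mass_action",
          setNames(1, paste0(e[["from"]], "*")),
          setNames(1, paste0(e[["to"]], "*")), e[["k"]], e[["comp"]],
          substrate = paste0(e[["from"]], "*"))
  }

  add("hepcidin_synthesis", "constant", c(), c(Hepcidin = 1), "kHepSyn", "plasma")
  add("hepcidin_degradation", "mass_action", c(Hepcidin = 1), c(),
      "kHepDeg", "plasma", substrate = "Hepcidin")

  rx
}

#' @export
print.iron_model <- function(x, ...) {
  cat("<iron_model> whole-body mouse iron distribution\n")
  cat("  species:   ", nrow(x$species),
      if (x$include_tracer) " (with 59Fe tracer twins)" else " (no tracer)",
      "\n", sep = "")
  cat("  reactions: ", length(x$reactions), "\n", sep = "")
  cat("  hepcidin steady level: ",
      format(x$params[["kHepSyn"]] / x$params[["kHepDeg"]] * 1e9, digits = 3),
      " nM\n", sep = "")
  invisible(x)
}

.volumes_of <- function(model) {
  v <- model$compartments$volume
  names(v) <- model$compartments$name
  v
}

#' Reaction fluxes and generic right-hand side
#'
#' `reaction_fluxes()` evaluates every reaction's extensive flux (mol/day)
#' at a state; `model_rhs()` assembles the per-species time derivatives by
#' signed stoichiometry, dividing by the home compartment volume for
#' concentration species (the `outside` pools are amounts and stay in
#' mol/day).  This reaction-by-reaction evaluator is the reference path;
#' simulation uses an equivalent compiled version (their agreement is
#' tested).
#'
#' @param model an [build_model()] object.
#' @param state named state vector (M for concentration species, mol for
#'   `FeOutside`/`FeOutside*`).
#' @param t time (days); the system is autonomous, present for the
#'   integrator interface.
#' @return named vector of fluxes, or of derivatives.
#' @export
reaction_fluxes <- function(model, state) {
  p <- model$params
  vol <- .volumes_of(model)
  hepfac <- 1 + state[["Hepcidin"]] / p[["Ki"]]
  vapply(model$reactions, function(r) {
    switch(r$kind,
      constant = p[[r$par]] * vol[[r$comp]],
      ferroportin = {
        S <- state[[r$substrate]]
        Ic <- if (is.null(r$competitor)) 0 else state[[r$competitor]]
        p[[r$par]] * vol[[r$comp]] * S /
          ((p[["Km"]] + S + Ic) * hepfac)
      },
      mass_action = p[[r$par]] * state[[r$substrate]] * vol[[r$comp]],
      bimolecular = {
        ab <- names(r$reactants)
        p[[r$par]] * state[[ab[1]]] * state[[ab[2]]] * vol[[r$comp]]
      },
      stop("unknown rate-law kind: ", r$kind)
    )
  }, numeric(1), USE.NAMES = FALSE) -> fl
  names(fl) <- vapply(model$reactions, `[[`, "", "name")
  fl
}

#' @rdname reaction_fluxes
#' @export
model_rhs <- function(model, state, t = 0) {
  if (anyNA(state)) stop("state contains NA/NaN")
  fl <- reaction_fluxes(model, state)
  d_amt <- setNames(numeric(nrow(model$species)), model$species$name)
  for (i in seq_along(model$reactions)) {
    r <- model$reactions[[i]]
    for (s in names(r$reactants))
      d_amt[s] <- d_amt[s] - r$reactants[[s]] * fl[[i]]
    for (s in names(r$products))
      d_amt[s] <- d_amt[s] + r$products[[s]] * fl[[i]]
  }
  vol <- .volumes_of(model)
  is_conc <- model$species$unit == "conc"
  d_amt[is_conc] <- d_amt[is_conc] /
    vol[model$species$compartment[is_conc]]
  d_amt
}

#' Default (pre-lead-in) model state
#'
#' All iron pools empty, transferrin entirely apo at `TfTotal`, hepcidin at
#' its synthesis/degradation steady level.  The de-novo lead-in fills the
#' iron pools from the dietary influx.
#'
#' @param model an `iron_model`.
#' @return named state vector.
#' @export
default_state <- function(model) {
  s <- setNames(numeric(nrow(model$species)), model$species$name)
  s[["Tf"]] <- model$params[["TfTotal"]]
  s[["Hepcidin"]] <- model$params[["kHepSyn"]] / model$params[["kHepDeg"]]
  s
}

#' Derived observables of a model state
#'
#' `total_iron()` sums every iron-carrying species (mono-ferric transferrin
#' counted once, di-ferric twice) over its compartment volume, excluding
#' the excreted `outside` pools, and converts to milligrams of iron.
#' `tf_saturation()` is the percentage of occupied transferrin binding
#' sites, `100 * (Fe1Tf + Fe1Tf* + 2 (Fe2Tf + Fe2Tf* + Fe2Tf**)) / (2
#' TfTotal)`.
#'
#' @param state named state vector.
#' @param model the `iron_model` the state belongs to.
#' @param include_outside also count excreted iron (then in mol-equivalent
#'   mass terms; used for whole-system bookkeeping).
#' @return milligrams of iron, or percent saturation.
#' @export
total_iron <- function(state, model, include_outside = FALSE) {
  sp <- model$species
  vol <- .volumes_of(model)
  fe <- sp$fe_u + sp$fe_l
  keep <- fe > 0 & (include_outside | sp$compartment != "outside")
  amt <- ifelse(sp$unit == "conc", state[sp$name] * vol[sp$compartment],
                state[sp$name])
  sum(fe[keep] * amt[keep]) * FE_MOLAR_MASS * 1000  # mol -> mg
}

#' @rdname total_iron
#' @export
tf_saturation <- function(state, model) {
  tot <- model$params[["TfTotal"]]
  stopifnot(tot > 0)
  g <- function(nm) if (nm %in% names(state)) state[[nm]] else 0
  100 * (g("Fe1Tf") + g("Fe1Tf*") +
           2 * (g("Fe2Tf") + g("Fe2Tf*") + g("Fe2Tf**"))) / (2 * tot)
}

#' Swap labeled and unlabeled species of a state
#'
#' Exchanges each iron pool with its isotopic twin (`Fe2Tf**` with
#' `Fe2Tf`, the mixed `Fe2Tf*` staying put).  Used to verify that
#' relabeling commutes with the dynamics.
#'
#' @param state named tracer-model state.
#' @return relabeled state.
#' @export
relabel_swap <- function(state) {
  nm <- names(state)
  out <- state
  starred <- grepl("\\*$", nm) & !(nm %in% c("Fe2Tf*", "Fe2Tf**"))
  base <- sub("\\*$", "", nm[starred])
  out[nm[starred]] <- state[base]
  out[base] <- state[nm[starred]]
  out[["Fe2Tf"]] <- state[["Fe2Tf**"]]
  out[["Fe2Tf**"]] <- state[["Fe2Tf"]]
  out
}
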