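# Programmatic builders for a set of worked example maps, plus a seeded
# random-map generator for property testing. Every builder is deterministic
# and returns a map that passes lenient validation with zero errors.
#
# The example maps encode what the underlying study descriptions state
# (figure captions, worked-example text, the culture-log template): where a
# published figure's full node roster is not enumerated in text, the map is a
# faithful skeleton of the named nodes and is marked "partial" in its
# metadata description.

IM_FIXTURES <- c("sulfidation", "mesocosm", "daphnia_culture", "oecd202",
                 "oecd211", "immunotox", "macrame_planning")

fx_sulfidation <- function() {
  m <- new_map("sulfidation", meta = list(
    description = paste("Synthesis of PVP-functionalised silver nanoparticles",
                        "by reduction of silver nitrate in ethylene glycol,",
                        "their physicochemical characterisation, and their",
                        "sulfidation at three PVP-AgNP concentrations giving",
                        "increasing S/Ag ratios"),
    keywords = c("AgNP", "PVP", "sulfidation", "synthesis"),
    version = "1"))
  # phase 1: the three synthesis instances
  m <- add_node(m, im_node("syn1", "Instance",
                           "AgNO3 in ethylene glycol",
                           fields = list(components = "silver nitrate; ethylene glycol")))
  m <- add_node(m, im_node("syn2", "Instance",
                           "Reduction in presence of 10k PVP",
                           fields = list(components = "AgNO3; ethylene glycol; PVP 10k")))
  m <- add_node(m, im_node("syn3", "Instance", "PVP-AgNP suspension",
                           fields = list(components = "PVP-AgNPs in ethylene glycol")))
  m <- add_edge(m, "syn1", "syn2")
  m <- add_edge(m, "syn2", "syn3")
  # pristine tracked variant and its characterisation branch
  m <- add_node(m, im_node("mat_pvp_agnp", "Material", "PVP-AgNP (pristine)",
                           fields = list(characterisation = "shape, size, crystalline phase",
                                         variant = "pristine")))
  m <- add_edge(m, "mat_pvp_agnp", "syn3")
  for (p in list(c("char_shape", "Particle shape"),
                 c("char_size", "Particle size"),
                 c("char_phase", "Crystalline phase"))) {
    m <- add_node(m, im_node(p[1], "ExperimentalProperty", p[2],
                             fields = list(assay = p[2])))
    m <- add_edge(m, "mat_pvp_agnp", p[1])
  }
  # phase 2: one transformation protocol per stated PVP-AgNP concentration,
  # same protocol otherwise; each yields a sulfidised material variant
  conc <- c(low = "low", mid = "intermediate", high = "high")
  for (k in names(conc)) {
    tp <- paste0("sulf_tp_", k)
    inst <- paste0("sulf_inst_", k)
    mat <- paste0("mat_sulf_", k)
    m <- add_node(m, im_node(tp, "TransformationProtocol",
                             sprintf("Sulfidation at %s PVP-AgNP concentration",
                                     conc[[k]]),
                             links = list(resource_link("protocols/sulfidation.md",
                                                        "protocol"))))
    m <- add_node(m, im_node(inst, "Instance",
                             sprintf("Sulfidised AgNPs (%s S/Ag ratio)", conc[[k]])))
    m <- add_node(m, im_node(mat, "Material",
                             sprintf("Sulfidised PVP-AgNP, %s S/Ag", conc[[k]]),
                             fields = list(characterisation = "S/Ag ratio",
                                           variant = paste0("sulfidised_", k))))
    m <- add_edge(m, "syn3", tp)
    m <- add_edge(m, tp, inst)
    m <- add_edge(m, mat, inst)
  }
  m <- add_region(m, im_region("phase_synthesis", "Synthesis of PVP-AgNPs",
                               members = c("syn1", "syn2", "syn3")))
  m <- add_region(m, im_region("phase_sulfidation", "Sulfidation",
                               members = c("sulf_tp_low", "sulf_tp_mid",
                                           "sulf_tp_high", "sulf_inst_low",
                                           "sulf_inst_mid", "sulf_inst_high")))
  m
}

fx_mesocosm <- function() {
  m <- new_map("mesocosm", meta = list(
    description = paste("Mesocosm exposure experiment: nanomaterial dispersion",
                        "and soil spiking, organism addition, and timed sample",
                        "collections with porewater, biomass and tissue-metal",
                        "analyses plus a transcriptomics extension. Partial",
                        "skeleton covering the named nodes only."),
    keywords = c("mesocosm", "soil", "ecotoxicology", "partial")))
  m <- add_node(m, im_node("meso1", "Instance",
                           "Set up - nanomaterial dispersion and soil spiking"))
  m <- add_node(m, im_node("meso2", "Instance", "Addition of organisms"))
  m <- add_node(m, im_node("meso3", "Instance", "Sample collection timepoint 1"))
  m <- add_edge(m, "meso1", "meso2")
  m <- add_edge(m, "meso2", "meso3")
  m <- add_node(m, im_node("mat_nm", "Material", "Pristine nanomaterial",
                           fields = list(characterisation = "supplier, batch number, CAS number")))
  m <- add_node(m, im_node("med_soil", "Medium", "Test soil",
                           fields = list(recipe = "soil type, pH, pre-processing")))
  m <- add_edge(m, "mat_nm", "meso1")
  m <- add_edge(m, "med_soil", "meso1")
  # pre-experiment / curated information (left side of the map)
  m <- add_node(m, im_node("cp_pre_nm", "CuratedProperty",
                           "Pre-experiment nanomaterial information",
                           fields = list(bibliography = "supplier data sheet")))
  m <- add_node(m, im_node("cp_culture", "CuratedProperty",
                           "Species and culture maintenance information",
                           fields = list(bibliography = "culture records")))
  m <- add_edge(m, "meso1", "cp_pre_nm")
  m <- add_edge(m, "meso2", "cp_culture")
  # generated data (right side): porewater chain
  m <- add_node(m, im_node("spp_porewater", "SamplePreparationProtocol",
                           "Soil porewater separation",
                           links = list(resource_link("protocols/porewater.md", "sop"))))
  m <- add_node(m, im_node("mp_metal", "MeasurementProtocol",
                           "Porewater metal concentration measurement"))
  m <- add_node(m, im_node("rd_porewater", "RawData",
                           "Porewater metal concentrations"))
  m <- add_node(m, im_node("dp_ec50", "DataProcessingProtocol",
                           "EC50 and bioaccumulation rate derivation"))
  m <- add_node(m, im_node("pd_rates", "ProcessedData",
                           "Metal bioaccumulation rates"))
  m <- add_edge(m, "meso3", "spp_porewater")
  m <- add_edge(m, "spp_porewater", "mp_metal")
  m <- add_edge(m, "mp_metal", "rd_porewater")
  m <- add_edge(m, "rd_porewater", "dp_ec50")
  m <- add_edge(m, "dp_ec50", "pd_rates")
  # tissue branch with transcriptomics extension
  m <- add_node(m, im_node("spp_tissue", "SamplePreparationProtocol",
                           "Tissue sample collection"))
  m <- add_node(m, im_node("mp_biomass", "MeasurementProtocol",
                           "Organism biomass measurement"))
  m <- add_node(m, im_node("rd_biomass", "RawData", "Organism biomass"))
  m <- add_node(m, im_node("mp_pcr", "MeasurementProtocol",
                           "Transcriptomics by real-time PCR"))
  m <- add_node(m, im_node("rd_pcr", "RawData", "Transcript abundance"))
  m <- add_edge(m, "meso3", "spp_tissue")
  m <- add_edge(m, "spp_tissue", "mp_biomass")
  m <- add_edge(m, "mp_biomass", "rd_biomass")
  m <- add_edge(m, "spp_tissue", "mp_pcr")
  m <- add_edge(m, "mp_pcr", "rd_pcr")
  m
}

fx_daphnia_culture <- function() {
  m <- new_map("daphnia_culture", meta = list(
    description = paste("Maintenance of continuous Daphnia magna cultures:",
                        "medium preparation and aeration, running culture",
                        "with daily feeding and offspring tracking, and",
                        "collection of third-brood neonates for toxicity",
                        "testing"),
    keywords = c("Daphnia magna", "culture", "QA/QC")))
  m <- add_node(m, im_node("med_hh", "Medium", "High hardness medium",
                           fields = list(
                             recipe = "high hardness medium, aerated >= 8 h before use",
                             medium_volume = "900 mL",
                             vessel = "1 L",
                             refresh = "three times per week")))
  m <- add_node(m, im_node("prep", "Instance", "Medium preparation and aeration",
                           fields = list(components = "high hardness medium",
                                         dissolved_oxygen_check = "every 2-3 days",
                                         ph_check = "before use")))
  m <- add_node(m, im_node("cult", "Instance", "Running D. magna culture",
                           fields = list(
                             components = "adult D. magna in high hardness medium",
                             adults = "10-15",
                             temperature = "20 \u00b0C",
                             photoperiod = "16:8",
                             food = "Chlorella vulgaris 7.5 mg C days 0-7, 11.25 mg C from day 7, double on Fridays")))
  m <- add_node(m, im_node("brood3", "Instance", "Third-brood neonates",
                           fields = list(components = "third-brood daphniids")))
  m <- add_edge(m, "prep", "cult")
  m <- add_edge(m, "cult", "brood3")
  m <- add_edge(m, "med_hh", "cult")
  m <- add_node(m, im_node("mat_algae", "Material",
                           "Chlorella vulgaris feed",
                           fields = list(characterisation = "algal carbon content")))
  m <- add_edge(m, "mat_algae", "cult")
  # daily QC: offspring tracking recorded on the culture-log template
  m <- add_node(m, im_node("spp_check", "SamplePreparationProtocol",
                           "Daily culture check",
                           links = list(resource_link("protocols/culture_check.md", "sop"))))
  m <- add_node(m, im_node("mp_count", "MeasurementProtocol",
                           "Offspring and adult counting"))
  m <- add_node(m, im_node("rd_log", "RawData", "Culture log",
                           links = list(resource_link("daphnia_culture_log.csv",
                                                      "raw_data",
                                                      media_hint = "CSV data capture template"))))
  m <- add_edge(m, "cult", "spp_check")
  m <- add_edge(m, "spp_check", "mp_count")
  m <- add_edge(m, "mp_count", "rd_log")
  m
}

fx_oecd202 <- function() {
  m <- new_map("oecd202", meta = list(
    description = paste("Daphnia sp. acute immobilisation test (OECD test",
                        "guideline 202): 48 h exposure of neonates to a",
                        "dilution series, immobilisation scoring, and",
                        "dose-response fitting"),
    keywords = c("OECD 202", "acute toxicity", "Daphnia")))
  m <- add_node(m, im_node("inst_neonates", "Instance",
                           "Daphnia neonates (<24 h old)",
                           fields = list(components = "third-brood neonates in test medium")))
  m <- add_node(m, im_node("inst_test", "Instance",
                           "Test vessels with exposure concentration series",
                           fields = list(components = "neonates; test medium; nanomaterial dilution series")))
  m <- add_node(m, im_node("inst_48h", "Instance", "48 h exposure endpoint"))
  m <- add_edge(m, "inst_neonates", "inst_test")
  m <- add_edge(m, "inst_test", "inst_48h")
  m <- add_node(m, im_node("mat_stock", "Material",
                           "Nanomaterial stock suspension",
                           fields = list(characterisation = "stock concentration; dispersion state")))
  m <- add_node(m, im_node("med_test", "Medium", "Test medium",
                           fields = list(recipe = "lab SOP medium (guideline recommends, does not mandate)")))
  m <- add_edge(m, "mat_stock", "inst_test")
  m <- add_edge(m, "med_test", "inst_test")
  m <- add_node(m, im_node("spp_score", "SamplePreparationProtocol",
                           "Vessel inspection set-up",
                           links = list(resource_link("protocols/oecd202_sop.md", "sop"))))
  m <- add_node(m, im_node("mp_immob", "MeasurementProtocol",
                           "Immobilisation count at 24 h and 48 h",
                           fields = list(instrument = "visual inspection")))
  m <- add_node(m, im_node("rd_counts", "RawData", "Immobilisation counts",
                           links = list(resource_link("templates/oecd202_data_capture.csv",
                                                      "raw_data"))))
  m <- add_node(m, im_node("dp_fit", "DataProcessingProtocol",
                           "Dose-response model fitting",
                           fields = list(statistical_test = "probit/logit regression")))
  m <- add_node(m, im_node("pd_dose_response", "ProcessedData",
                           "Acute dose-response curve (EC50/EC10)",
                           fields = list(processed_data = "EC50, EC10 with confidence intervals")))
  m <- add_edge(m, "inst_48h", "spp_score")
  m <- add_edge(m, "spp_score", "mp_immob")
  m <- add_edge(m, "mp_immob", "rd_counts")
  m <- add_edge(m, "rd_counts", "dp_fit")
  m <- add_edge(m, "dp_fit", "pd_dose_response")
  m
}

fx_oecd211 <- function() {
  m <- new_map("oecd211", meta = list(
    description = paste("Daphnia magna reproduction test (OECD test guideline",
                        "211): 21 d chronic exposure at a concentration",
                        "derived from the acute dose-response curve of the",
                        "acute immobilisation test"),
    keywords = c("OECD 211", "chronic toxicity", "reproduction")))
  m <- add_node(m, im_node("inst_adults", "Instance",
                           "Adult daphnia from running culture"))
  m <- add_node(m, im_node("inst_exposure", "Instance",
                           "Chronic exposure vessels (21 d)",
                           fields = list(components = "adults; test medium; nanomaterial at derived concentration")))
  m <- add_node(m, im_node("inst_offspring", "Instance",
                           "Offspring production over 21 d"))
  m <- add_edge(m, "inst_adults", "inst_exposure")
  m <- add_edge(m, "inst_exposure", "inst_offspring")
  m <- add_node(m, im_node("mat_stock211", "Material",
                           "Nanomaterial stock suspension",
                           fields = list(
                             characterisation = "stock concentration",
                             exposure_concentration = "EC10 from acute dose-response")))
  m <- add_node(m, im_node("med_211", "Medium", "Test medium",
                           fields = list(recipe = "lab SOP medium")))
  m <- add_edge(m, "mat_stock211", "inst_exposure")
  m <- add_edge(m, "med_211", "inst_exposure")
  m <- add_node(m, im_node("spp_211", "SamplePreparationProtocol",
                           "Offspring separation and counting set-up"))
  m <- add_node(m, im_node("mp_repro", "MeasurementProtocol",
                           "Offspring counts per female"))
  m <- add_node(m, im_node("rd_repro", "RawData", "Reproduction counts"))
  m <- add_node(m, im_node("dp_repro", "DataProcessingProtocol",
                           "Reproductive endpoint derivation"))
  m <- add_node(m, im_node("pd_repro", "ProcessedData",
                           "Chronic reproduction endpoints"))
  m <- add_edge(m, "inst_offspring", "spp_211")
  m <- add_edge(m, "spp_211", "mp_repro")
  m <- add_edge(m, "mp_repro", "rd_repro")
  m <- add_edge(m, "rd_repro", "dp_repro")
  m <- add_edge(m, "dp_repro", "pd_repro")
  # the chronic exposure concentration comes from the acute test's curve
  m <- add_map_link(m, im_map_link("mat_stock211", "oecd202",
                                   "pd_dose_response",
                                   "exposure concentration determined from acute dose-response curve"))
  m
}

fx_immunotox <- function() {
  m <- new_map("immunotox", meta = list(
    description = paste("Immunotoxicity workflow for differently",
                        "functionalised SiO2 nanomaterials and immune cells,",
                        "divided into sections A-E: synthesis and",
                        "characterisation baseline (A), antigen-presenting",
                        "cell activation (B), protein binding (C),",
                        "in silico corona prediction (D), nanotopography and",
                        "epitope integrity (E). Partial skeleton."),
    keywords = c("SiO2", "immunotoxicity", "protein corona", "partial")))
  # section A: baseline synthesis, functionalisation, characterisation
  m <- add_node(m, im_node("inst_syn", "Instance",
                           "SiO2 NP synthesis (Stober or emulsion method)"))
  m <- add_node(m, im_node("inst_func", "Instance",
                           "Surface functionalisation (amino/carboxyl linkers)"))
  m <- add_node(m, im_node("inst_char", "Instance",
                           "Characterised SiO2 nanomaterials"))
  m <- add_edge(m, "inst_syn", "inst_func")
  m <- add_edge(m, "inst_func", "inst_char")
  m <- add_node(m, im_node("mat_sio2", "Material", "SiO2 NPs, 50-100 nm",
                           fields = list(characterisation = "size, surface modification, zeta potential")))
  m <- add_edge(m, "mat_sio2", "inst_char")
  m <- add_node(m, im_node("ep_size", "ExperimentalProperty",
                           "Size distribution (TEM, NTA, DLS)",
                           fields = list(assay = "TEM/NTA/DLS")))
  m <- add_edge(m, "inst_char", "ep_size")
  # section B: APC activation profile
  m <- add_node(m, im_node("inst_apc", "Instance",
                           "Monocyte-derived dendritic cells (APC model)"))
  m <- add_node(m, im_node("inst_incub", "Instance",
                           "APCs incubated with functionalised NPs"))
  m <- add_edge(m, "inst_char", "inst_incub")
  m <- add_edge(m, "inst_apc", "inst_incub")
  m <- add_node(m, im_node("spp_b", "SamplePreparationProtocol",
                           "Cell harvest and staining"))
  m <- add_node(m, im_node("mp_flow", "MeasurementProtocol",
                           "Flow cytometry and ELISA"))
  m <- add_node(m, im_node("rd_b", "RawData", "Activation marker data"))
  m <- add_node(m, im_node("dp_b", "DataProcessingProtocol",
                           "Gating and statistics"))
  m <- add_node(m, im_node("pd_b", "ProcessedData",
                           "Immunologic activation profile"))
  m <- add_edge(m, "inst_incub", "spp_b")
  m <- add_edge(m, "spp_b", "mp_flow")
  m <- add_edge(m, "mp_flow", "rd_b")
  m <- add_edge(m, "rd_b", "dp_b")
  m <- add_edge(m, "dp_b", "pd_b")
  # section C: protein binding capacity
  m <- add_node(m, im_node("inst_conj", "Instance",
                           "NP-protein conjugates"))
  m <- add_edge(m, "inst_char", "inst_conj")
  m <- add_node(m, im_node("ep_binding", "ExperimentalProperty",
                           "Protein binding capacity (gel electrophoresis)",
                           fields = list(assay = "gel electrophoresis; supernatant quantification")))
  m <- add_edge(m, "inst_conj", "ep_binding")
  # section D: in silico corona prediction
  m <- add_node(m, im_node("cp_corona", "ComputedProperty",
                           "Predicted protein corona composition",
                           fields = list(model = "protein corona prediction tools")))
  m <- add_edge(m, "inst_char", "cp_corona")
  # section E: nanotopography and epitope integrity
  m <- add_node(m, im_node("inst_meso", "Instance",
                           "Mesoporous SiO2 NPs (CTAB pore formation)"))
  m <- add_edge(m, "inst_syn", "inst_meso")
  m <- add_node(m, im_node("ep_epitope", "ExperimentalProperty",
                           "Epitope integrity upon conjugation",
                           fields = list(assay = "epitope mapping")))
  m <- add_edge(m, "inst_meso", "ep_epitope")
  secs <- list(A = c("inst_syn", "inst_func", "inst_char", "mat_sio2", "ep_size"),
               B = c("inst_apc", "inst_incub", "spp_b", "mp_flow", "rd_b",
                     "dp_b", "pd_b"),
               C = c("inst_conj", "ep_binding"),
               D = c("cp_corona"),
               E = c("inst_meso", "ep_epitope"))
  for (s in names(secs))
    m <- add_region(m, im_region(s, s, members = secs[[s]]))
  m
}

fx_macrame_planning <- function() {
  red <- IM_CATEGORIES$data  # data-red deliberately misapplied to flag open points
  m <- new_map("macrame_planning", meta = list(
    description = paste("Planning status of human and ecotoxicology testing",
                        "for antibiotics-loaded polymeric nanomaterials in a",
                        "multi-partner project: production, shipping to",
                        "testing partners, and assay chains, with data-red",
                        "colour overrides marking steps still under",
                        "discussion. Partial skeleton."),
    keywords = c("planning", "shipping", "multi-partner", "partial")))
  m <- add_node(m, im_node("inst_prod", "Instance",
                           "Production of antibiotics-loaded polymeric NPs"))
  m <- add_node(m, im_node("mat_np", "Material",
                           "Antibiotics-loaded polymeric NPs",
                           fields = list(characterisation = "loading, size, polymer matrix")))
  m <- add_edge(m, "mat_np", "inst_prod")
  # shipping steps are transformation protocols between partner instances
  partners <- list(tox = "human toxicity partner", eco = "ecotoxicity partner")
  for (k in names(partners)) {
    tp <- paste0("tp_ship_", k)
    inst <- paste0("inst_", k)
    m <- add_node(m, im_node(tp, "TransformationProtocol",
                             sprintf("Shipping of pristine material to %s",
                                     partners[[k]]),
                             fields = list(protocol = "shipping and chain-of-custody record")))
    m <- add_node(m, im_node(inst, "Instance",
                             sprintf("Material received at %s", partners[[k]])))
    m <- add_edge(m, "inst_prod", tp)
    m <- add_edge(m, tp, inst)
  }
  m <- add_node(m, im_node("spp_aerosol", "SamplePreparationProtocol",
                           "Aerosol generation for lung model exposure"))
  m <- add_node(m, im_node("mp_lung", "MeasurementProtocol",
                           "In vitro lung model exposure and quantification"))
  m <- add_node(m, im_node("rd_lung", "RawData", "Aerosol exposure data"))
  m <- add_edge(m, "inst_tox", "spp_aerosol")
  m <- add_edge(m, "spp_aerosol", "mp_lung")
  m <- add_edge(m, "mp_lung", "rd_lung")
  # planning nodes: non-data kinds shown in data-red to mark open discussions
  m <- add_node(m, im_node("plan_timing", "MeasurementProtocol",
                           "Aerosol measurement timing - to be discussed",
                           colour_override = red))
  m <- add_node(m, im_node("plan_budget", "SamplePreparationProtocol",
                           "Ecotox sample preparation - feasibility within budget open",
                           colour_override = red))
  m <- add_edge(m, "inst_tox", "plan_timing")
  m <- add_edge(m, "inst_eco", "plan_budget")
  m
}

#' Build a packaged example map
#'
#' Deterministic builders for seven worked example maps spanning the format's
#' use cases: nanoparticle synthesis and sulfidation
#' (\code{"sulfidation"}), a soil mesocosm exposure (\code{"mesocosm"}),
#' maintenance of \emph{Daphnia magna} cultures
#' (\code{"daphnia_culture"}), the acute and chronic daphnia toxicity test
#' guidelines (\code{"oecd202"}, \code{"oecd211"}, the latter cross-linking
#' into the former), an immunotoxicity workflow with annotation regions A-E
#' (\code{"immunotox"}), and a multi-partner project-planning map with
#' shipping steps and colour-override planning nodes
#' (\code{"macrame_planning"}).
#'
#' @param name One of \code{fixture_names()}.
#' @return An instance map; identical across calls.
#' @examples
#' m <- build_fixture("sulfidation")
#' length(nodes_of_kind(m, "TransformationProtocol"))
#' @export
build_fixture <- function(name) {
  if (length(name) != 1L || !name %in% IM_FIXTURES)
    im_stop("E_UNKNOWN_FIXTURE", "unknown fixture: %s",
            paste(as.character(name), collapse = ", "))
  switch(name,
         sulfidation = fx_sulfidation(),
         mesocosm = fx_mesocosm(),
         daphnia_culture = fx_daphnia_culture(),
         oecd202 = fx_oecd202(),
         oecd211 = fx_oecd211(),
         immunotox = fx_immunotox(),
         macrame_planning = fx_macrame_planning())
}

#' @rdname build_fixture
#' @export
fixture_names <- function() IM_FIXTURES

#' Generate a random instance map
#'
#' Builds a backbone of \code{n_instances} chained Instance nodes and, with
#' probability \code{branch_prob} per instance and branch type, attaches a
#' material, a medium, a property node, and/or a measurement chain (sample
#' preparation, measurement, raw data, optionally data processing and
#' processed data). All edges point forward, so the result is always acyclic
#' and passes lenient validation with zero errors. The generator restores the
#' caller's RNG state: the same seed always yields the identical map.
#'
#' @param seed Integer seed.
#' @param n_instances Number of backbone instances (>= 0).
#' @param branch_prob Probability in [0, 1] of each side branch.
#' @return An instance map with id \code{"random_<seed>"}.
#' @export
random_map <- function(seed, n_instances = 5, branch_prob = 0.5) {
  stopifnot(n_instances >= 0, branch_prob >= 0, branch_prob <= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- new_map(sprintf("random_%d", seed))
  prev <- NULL
  props <- IM_PROPERTY_KINDS
  for (i in seq_len(n_instances)) {
    id <- sprintf("inst_%03d", i)
    m <- add_node(m, im_node(id, "Instance", sprintf("Instance %d", i),
                             fields = list(components = sprintf("state %d", i))))
    if (!is.null(prev)) m <- add_edge(m, prev, id)
    prev <- id
    if (stats::runif(1) < branch_prob) {
      mid <- sprintf("mat_%03d", i)
      m <- add_node(m, im_node(mid, "Material", sprintf("Material %d", i),
                               fields = list(characterisation = "synthetic")))
      m <- add_edge(m, mid, id)
    }
    if (stats::runif(1) < branch_prob) {
      med <- sprintf("med_%03d", i)
      m <- add_node(m, im_node(med, "Medium", sprintf("Medium %d", i),
                               fields = list(recipe = "synthetic")))
      m <- add_edge(m, med, id)
    }
    if (stats::runif(1) < branch_prob) {
      pk <- sample(props, 1)
      pid <- sprintf("prop_%03d", i)
      m <- add_node(m, im_node(pid, pk, sprintf("Property %d", i)))
      m <- add_edge(m, id, pid)
    }
    if (stats::runif(1) < branch_prob) {
      sp <- sprintf("spp_%03d", i); mp <- sprintf("mp_%03d", i)
      rd <- sprintf("rd_%03d", i)
      m <- add_node(m, im_node(sp, "SamplePreparationProtocol"))
      m <- add_node(m, im_node(mp, "MeasurementProtocol"))
      m <- add_node(m, im_node(rd, "RawData"))
      m <- add_edge(m, id, sp)
      m <- add_edge(m, sp, mp)
      m <- add_edge(m, mp, rd)
      if (stats::runif(1) < 0.5) {
        dp <- sprintf("dp_%03d", i); pd <- sprintf("pd_%03d", i)
        m <- add_node(m, im_node(dp, "DataProcessingProtocol"))
        m <- add_node(m, im_node(pd, "ProcessedData"))
        m <- add_edge(m, rd, dp)
        m <- add_edge(m, dp, pd)
      }
    }
  }
  m
}
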