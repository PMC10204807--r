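## Curated synthetic C3-leaf core model: four internal compartments
## (cytosol c, chloroplast h, mitochondrion m, peroxisome x) plus the
## external space e. Hand-written reaction list; only the biomass equation
## is assembled from the configuration.

#' Configuration of the synthetic leaf model
#'
#' @param biomass_fractions named mass fractions (must sum to 1) of
#'   `carbohydrate`, `protein`, `fiber`, `lipid`. The defaults are
#'   placeholder values for a generic mature C3 leaf, not a measured
#'   composition; override them to match tissue data.
#' @param net_photosynthesis baseline net CO2 assimilation P_N
#'   (mmol CO2/gDW/day).
#' @param lue light-use efficiency (mol CO2 per mol photons). `NULL`
#'   (default) calibrates the photon budget to the model's own optimal
#'   photon demand at `net_photosynthesis` (see
#'   [build_fixture_leaf_model()]); a numeric value uses
#'   `net_photosynthesis / lue` directly.
#' @param maintenance_atp non-growth ATP maintenance flux, pinned
#'   (mmol/gDW/day).
#' @param vc_vo_default RuBisCO carboxylation/oxygenation ratio attached to
#'   the model (ambient-air value 3).
#' @param seed integer seed used by [synth_expression()] consumers.
#' @return object of class `fixture_config`.
#' @export
fixture_config <- function(biomass_fractions = c(carbohydrate = 0.55,
                                                 protein = 0.20,
                                                 fiber = 0.17,
                                                 lipid = 0.08),
                           net_photosynthesis = 100,
                           lue = NULL,
                           maintenance_atp = 7.5,
                           vc_vo_default = 3,
                           seed = 1L) {
  need <- c("carbohydrate", "protein", "fiber", "lipid")
  if (!all(need %in% names(biomass_fractions)))
    stop("biomass_fractions needs carbohydrate, protein, fiber and lipid")
  if (abs(sum(biomass_fractions) - 1) > 1e-9)
    stop("biomass fractions must sum to 1")
  if (net_photosynthesis <= 0 || maintenance_atp <= 0 || vc_vo_default <= 0)
    stop("rates must be positive")
  if (!is.null(lue) && lue <= 0) stop("lue must be positive")
  structure(list(biomass_fractions = biomass_fractions[need],
                 net_photosynthesis = net_photosynthesis, lue = lue,
                 maintenance_atp = maintenance_atp,
                 vc_vo_default = vc_vo_default, seed = as.integer(seed)),
            class = "fixture_config")
}

#' Write / read a fixture configuration as JSON
#' @param config a [fixture_config()].
#' @param path JSON file path.
#' @return `path` / the configuration.
#' @export
write_fixture_config <- function(config, path) {
  x <- unclass(config)
  x$biomass_fractions <- as.list(x$biomass_fractions)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fixture_config
#' @export
read_fixture_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixture_config(biomass_fractions = unlist(x$biomass_fractions),
                 net_photosynthesis = x$net_photosynthesis,
                 lue = x$lue, maintenance_atp = x$maintenance_atp,
                 vc_vo_default = x$vc_vo_default, seed = x$seed)
}

## residue/monomer molecular weights (g/mol) used to turn mass fractions
## into mmol/gDW coefficients: anhydroglucose units for starch and
## cellulose, a mean amino-acid residue, palmitate for lipid
fixture_mw <- c(carbohydrate = 162.14, protein = 110.0, fiber = 162.14,
                lipid = 256.43)

fixture_metabolites <- function() {
  m <- function(id, name, comp, formula, ann = NA_character_)
    data.frame(id = id, name = name, compartment = comp, formula = formula,
               boundary = FALSE, annotation = ann, stringsAsFactors = FALSE)
  rbind(
    ## external space
    m("co2_e", "CO2 (external)", "e", "C", "co2"),
    m("o2_e", "O2 (external)", "e", "O2", "o2"),
    m("h2o_e", "water (external)", "e", "H2O", "water"),
    m("photon_e", "photon (external)", "e", "Z0", "photon"),
    m("no3_e", "nitrate (external)", "e", "N", "nitrogen"),
    m("pi_e", "phosphate (external)", "e", "P", "pi"),
    m("so4_e", "sulfate (external)", "e", "S", "sulfur"),
    m("nh4_e", "ammonium (external)", "e", "N", "ammonium"),
    m("sucrose_e", "sucrose (exported)", "e", "C12", "sucrose"),
    ## chloroplast
    m("photon_h", "photon", "h", "Z0", "photon"),
    m("co2_h", "CO2", "h", "C", "co2"),
    m("o2_h", "O2", "h", "O2", "o2"),
    m("h2o_h", "water", "h", "H2O", "water"),
    m("atp_h", "ATP", "h", "C10N5P3", "atp"),
    m("adp_h", "ADP", "h", "C10N5P2", "adp"),
    m("pi_h", "phosphate", "h", "P", "pi"),
    m("nadp_h", "NADP+", "h", "C21N7P3", "nadp"),
    m("nadph_h", "NADPH", "h", "C21N7P3", "nadph"),
    m("rubp_h", "ribulose 1,5-bisphosphate", "h", "C5P2"),
    m("pga_h", "3-phosphoglycerate", "h", "C3P"),
    m("gap_h", "triose phosphate", "h", "C3P"),
    m("fbp_h", "fructose 1,6-bisphosphate", "h", "C6P2"),
    m("f6p_h", "fructose 6-phosphate", "h", "C6P"),
    m("g6p_h", "glucose 6-phosphate", "h", "C6P"),
    m("g1p_h", "glucose 1-phosphate", "h", "C6P"),
    m("adpglc_h", "ADP-glucose", "h", "C16N5P2"),
    m("starch_h", "starch (glucan unit)", "h", "C6"),
    m("pglyc_h", "2-phosphoglycolate", "h", "C2P"),
    m("glyc_h", "glycolate", "h", "C2"),
    m("glyca_h", "glycerate", "h", "C3"),
    m("pep_h", "phosphoenolpyruvate", "h", "C3P"),
    m("pyr_h", "pyruvate", "h", "C3"),
    m("oaa_h", "oxaloacetate", "h", "C4"),
    m("mal_h", "malate", "h", "C4"),
    m("akg_h", "2-oxoglutarate", "h", "C5"),
    m("glu_h", "glutamate", "h", "C5N"),
    m("gln_h", "glutamine", "h", "C5N2"),
    m("nh4_h", "ammonium", "h", "N", "ammonium"),
    m("no2_h", "nitrite", "h", "N"),
    m("fa_h", "fatty acid (C16)", "h", "C16"),
    ## cytosol
    m("co2_c", "CO2", "c", "C", "co2"),
    m("hco3_c", "bicarbonate", "c", "C", "hco3"),
    m("o2_c", "O2", "c", "O2", "o2"),
    m("h2o_c", "water", "c", "H2O", "water"),
    m("atp_c", "ATP", "c", "C10N5P3", "atp"),
    m("adp_c", "ADP", "c", "C10N5P2", "adp"),
    m("pi_c", "phosphate", "c", "P", "pi"),
    m("nad_c", "NAD+", "c", "C21N7P2", "nad"),
    m("nadh_c", "NADH", "c", "C21N7P2", "nadh"),
    m("nadp_c", "NADP+", "c", "C21N7P3", "nadp"),
    m("nadph_c", "NADPH", "c", "C21N7P3", "nadph"),
    m("gap_c", "triose phosphate", "c", "C3P"),
    m("pga_c", "3-phosphoglycerate", "c", "C3P"),
    m("pep_c", "phosphoenolpyruvate", "c", "C3P"),
    m("pyr_c", "pyruvate", "c", "C3"),
    m("oaa_c", "oxaloacetate", "c", "C4"),
    m("mal_c", "malate", "c", "C4"),
    m("akg_c", "2-oxoglutarate", "c", "C5"),
    m("glu_c", "glutamate", "c", "C5N"),
    m("gln_c", "glutamine", "c", "C5N2"),
    m("asp_c", "aspartate", "c", "C4N"),
    m("ser_c", "serine", "c", "C3N"),
    m("gly_c", "glycine", "c", "C2N"),
    m("cys_c", "cysteine", "c", "C3NS"),
    m("g6p_c", "glucose 6-phosphate", "c", "C6P"),
    m("f6p_c", "fructose 6-phosphate", "c", "C6P"),
    m("fbp_c", "fructose 1,6-bisphosphate", "c", "C6P2"),
    m("g1p_c", "glucose 1-phosphate", "c", "C6P"),
    m("udpg_c", "NDP-glucose (lumped)", "c", "C16N5P2"),
    m("s6p_c", "sucrose 6-phosphate", "c", "C12P"),
    m("sucrose_c", "sucrose", "c", "C12", "sucrose"),
    m("ru5p_c", "ribulose 5-phosphate", "c", "C5P"),
    m("cellulose_c", "cellulose (glucan unit)", "c", "C6"),
    m("protein_c", "protein (residue mix)", "c", NA_character_),
    m("no3_c", "nitrate", "c", "N", "nitrogen"),
    m("so4_c", "sulfate", "c", "S", "sulfur"),
    m("no2_c", "nitrite", "c", "N"),
    m("nh4_c", "ammonium", "c", "N", "ammonium"),
    m("biomass_c", "leaf biomass", "c", NA_character_, "biomass"),
    ## mitochondrion
    m("co2_m", "CO2", "m", "C", "co2"),
    m("o2_m", "O2", "m", "O2", "o2"),
    m("atp_m", "ATP", "m", "C10N5P3", "atp"),
    m("adp_m", "ADP", "m", "C10N5P2", "adp"),
    m("pi_m", "phosphate", "m", "P", "pi"),
    m("nad_m", "NAD+", "m", "C21N7P2", "nad"),
    m("nadh_m", "NADH", "m", "C21N7P2", "nadh"),
    m("pyr_m", "pyruvate", "m", "C3"),
    m("coa_m", "coenzyme A", "m", "C21N7P3S"),
    m("accoa_m", "acetyl-CoA", "m", "C23N7P3S"),
    m("cit_m", "citrate", "m", "C6"),
    m("akg_m", "2-oxoglutarate", "m", "C5"),
    m("mal_m", "malate", "m", "C4"),
    m("oaa_m", "oxaloacetate", "m", "C4"),
    m("gly_m", "glycine", "m", "C2N"),
    m("ser_m", "serine", "m", "C3N"),
    m("nh4_m", "ammonium", "m", "N", "ammonium"),
    ## peroxisome
    m("o2_x", "O2", "x", "O2", "o2"),
    m("glyc_x", "glycolate", "x", "C2"),
    m("glyox_x", "glyoxylate", "x", "C2"),
    m("gly_x", "glycine", "x", "C2N"),
    m("ser_x", "serine", "x", "C3N"),
    m("hpyr_x", "hydroxypyruvate", "x", "C3"),
    m("glyca_x", "glycerate", "x", "C3"),
    m("mal_x", "malate", "x", "C4"),
    m("oaa_x", "oxaloacetate", "x", "C4"),
    m("nad_x", "NAD+", "x", "C21N7P2", "nad"),
    m("nadh_x", "NADH", "x", "C21N7P2", "nadh"),
    m("glu_x", "glutamate", "x", "C5N"),
    m("akg_x", "2-oxoglutarate", "x", "C5")
  )
}

fixture_reactions <- function() {
  r <- function(id, name, eq, lb, ub, gpr = NA_character_,
                pathway = "transport", ec = NA_character_)
    data.frame(id = id, name = name, equation = eq, lb = lb, ub = ub,
               gpr = gpr, pathway = pathway, ec = ec, stringsAsFactors = FALSE)
  BIG <- 1e6
  rbind(
    ## exchanges (export-positive)
    r("EX_co2", "CO2 exchange", "co2_e ->", -1000, 1000, pathway = "exchange"),
    r("EX_o2", "O2 exchange", "o2_e ->", -1000, 1000, pathway = "exchange"),
    r("EX_h2o", "water exchange", "h2o_e ->", -BIG, BIG, pathway = "exchange"),
    r("EX_photon", "photon exchange", "photon_e ->", -BIG, 0, pathway = "exchange"),
    r("EX_no3", "nitrate exchange", "no3_e ->", -1000, 1000, pathway = "exchange"),
    r("EX_pi", "phosphate exchange", "pi_e ->", -1000, 1000, pathway = "exchange"),
    r("EX_so4", "sulfate exchange", "so4_e ->", -1000, 1000, pathway = "exchange"),
    r("EX_nh4", "ammonium export (closed)", "nh4_e ->", 0, 0, pathway = "exchange"),
    r("EX_sucrose", "sucrose export", "sucrose_e ->", 0, 1000, pathway = "exchange"),
    r("DM_biomass", "biomass drain", "biomass_c ->", 0, 1000, pathway = "exchange"),
    ## gas / small-molecule diffusion and transport
    r("T_co2_ec", "CO2 diffusion e/c", "co2_e <=> co2_c", -1000, 1000),
    r("T_co2_ch", "CO2 diffusion c/h", "co2_c <=> co2_h", -1000, 1000),
    r("T_co2_cm", "CO2 diffusion c/m", "co2_c <=> co2_m", -1000, 1000),
    r("T_o2_ec", "O2 diffusion e/c", "o2_e <=> o2_c", -1000, 1000),
    r("T_o2_ch", "O2 diffusion c/h", "o2_c <=> o2_h", -1000, 1000),
    r("T_o2_cm", "O2 diffusion c/m", "o2_c <=> o2_m", -1000, 1000),
    r("T_o2_cx", "O2 diffusion c/x", "o2_c <=> o2_x", -1000, 1000),
    ## water crosses membranes freely
    r("T_h2o_ec", "water transport e/c", "h2o_e <=> h2o_c", -BIG, BIG),
    r("T_h2o_ch", "water transport c/h", "h2o_c <=> h2o_h", -BIG, BIG),
    r("T_photon_eh", "photon capture", "photon_e -> photon_h", 0, BIG),
    r("T_no3_ec", "nitrate uptake", "no3_e <=> no3_c", -1000, 1000),
    r("T_pi_ec", "phosphate uptake", "pi_e <=> pi_c", -1000, 1000),
    r("T_pi_ch", "phosphate transport c/h", "pi_c <=> pi_h", -1000, 1000),
    r("T_pi_cm", "phosphate transport c/m", "pi_c <=> pi_m", -1000, 1000),
    r("T_so4_ec", "sulfate uptake", "so4_e <=> so4_c", -1000, 1000),
    r("T_nh4_ce", "ammonium efflux", "nh4_c -> nh4_e", 0, 1000),
    r("T_sucr_ce", "sucrose phloem loading", "sucrose_c -> sucrose_e", 0, 1000),
    r("TPT_ch", "triose phosphate translocator",
      "gap_h + pi_c <=> gap_c + pi_h", -1000, 1000),
    ## export-only in the light: daytime stromal adenylate import is
    ## inactive; the stroma tops up ATP via cyclic electron flow
    r("AAC_hc", "ATP/ADP translocator (chloroplast, export)",
      "atp_h + adp_c -> atp_c + adp_h", 0, BIG),
    r("AAC_mc", "ATP/ADP translocator (mitochondrion)",
      "atp_m + adp_c <=> atp_c + adp_m", -BIG, BIG),
    r("T_mal_hc", "malate transport h/c", "mal_h <=> mal_c", -1000, 1000),
    r("T_oaa_ch", "oxaloacetate transport c/h", "oaa_c <=> oaa_h", -1000, 1000),
    r("T_mal_mc", "malate transport m/c", "mal_m <=> mal_c", -1000, 1000),
    r("T_oaa_cm", "oxaloacetate transport c/m", "oaa_c <=> oaa_m", -1000, 1000),
    r("T_mal_cx", "malate transport c/x", "mal_c <=> mal_x", -1000, 1000),
    r("T_oaa_xc", "oxaloacetate transport x/c", "oaa_x <=> oaa_c", -1000, 1000),
    r("T_pyr_ch", "pyruvate transport c/h", "pyr_c <=> pyr_h", -1000, 1000),
    r("T_pyr_cm", "pyruvate transport c/m", "pyr_c <=> pyr_m", -1000, 1000),
    r("T_glu_hc", "glutamate transport h/c", "glu_h <=> glu_c", -1000, 1000),
    r("T_gln_hc", "glutamine transport h/c", "gln_h <=> gln_c", -1000, 1000),
    r("T_akg_ch", "2-oxoglutarate transport c/h", "akg_c <=> akg_h", -1000, 1000),
    r("T_akg_mc", "2-oxoglutarate transport m/c", "akg_m <=> akg_c", -1000, 1000),
    r("T_akg_xc", "2-oxoglutarate transport x/c", "akg_x <=> akg_c", -1000, 1000),
    r("T_glu_cx", "glutamate transport c/x", "glu_c <=> glu_x", -1000, 1000),
    r("T_ser_mx", "serine transport m/x", "ser_m <=> ser_x", -1000, 1000),
    r("T_gly_xm", "glycine transport x/m", "gly_x <=> gly_m", -1000, 1000),
    r("T_ser_mc", "serine transport m/c", "ser_m <=> ser_c", -1000, 1000),
    r("T_gly_mc", "glycine transport m/c", "gly_m <=> gly_c", -1000, 1000),
    r("T_glyc_hx", "glycolate transport h/x", "glyc_h -> glyc_x", 0, 1000),
    r("T_glyca_xh", "glycerate transport x/h", "glyca_x -> glyca_h", 0, 1000),
    r("T_no2_ch", "nitrite transport c/h", "no2_c <=> no2_h", -1000, 1000),
    r("T_nh4_mc", "ammonium transport m/c", "nh4_m <=> nh4_c", -1000, 1000),
    r("T_nh4_ch", "ammonium transport c/h", "nh4_c <=> nh4_h", -1000, 1000),
    ## photosynthetic light reactions
    r("LEF_h", "linear electron flow (lumped)",
      paste("4 photon_h + nadp_h + 1.28 adp_h + 1.28 pi_h + h2o_h ->",
            "nadph_h + 1.28 atp_h + 0.5 o2_h"),
      0, BIG, "g_psab1 or g_psab2", "light_reactions"),
    ## cyclic flow tops up stromal ATP but is a minor fraction of the
    ## chain in vivo; its capacity bound forces surplus absorbed light
    ## beyond it into the carbon network
    r("CEF_h", "cyclic electron flow (lumped)",
      "2 photon_h + adp_h + pi_h -> atp_h", 0, 150, "g_pgr5",
      "light_reactions"),
    ## Calvin-Benson cycle
    r("RBC_carb", "RuBisCO carboxylase (Vc)",
      "rubp_h + co2_h + h2o_h -> 2 pga_h", 0, 1000,
      "g_rbcl and (g_rbcs1 or g_rbcs2)", "calvin_cycle", "4.1.1.39"),
    r("RBC_oxy", "RuBisCO oxygenase (Vo)",
      "rubp_h + o2_h -> pga_h + pglyc_h", 0, 1000,
      "g_rbcl and (g_rbcs1 or g_rbcs2)", "photorespiration", "4.1.1.39"),
    r("PGK_GAPDH_h", "phosphoglycerate reduction (lumped)",
      "pga_h + atp_h + nadph_h -> gap_h + adp_h + pi_h + nadp_h",
      0, 1000, "g_pgk_h and g_gapa", "calvin_cycle", "1.2.1.13"),
    r("CBB_regen", "RuBP regeneration (lumped)",
      "5 gap_h + 3 atp_h -> 3 rubp_h + 3 adp_h + 2 pi_h",
      0, 1000, "g_prk and g_tkl", "calvin_cycle", "2.7.1.19"),
    r("ALD_h", "plastid aldolase", "2 gap_h <=> fbp_h", -1000, 1000,
      "g_fba_h", "calvin_cycle", "4.1.2.13"),
    r("FBPase_h", "plastid fructose bisphosphatase",
      "fbp_h + h2o_h -> f6p_h + pi_h", 0, 1000, "g_fbp_h", "calvin_cycle",
      "3.1.3.11"),
    r("PGI_h", "plastid phosphoglucose isomerase", "f6p_h <=> g6p_h",
      -1000, 1000, "g_pgi_h", "starch_sucrose", "5.3.1.9"),
    r("PGM_h", "plastid phosphoglucomutase", "g6p_h <=> g1p_h",
      -1000, 1000, "g_pgm_h", "starch_sucrose", "5.4.2.2"),
    r("AGP_h", "ADP-glucose pyrophosphorylase",
      "g1p_h + atp_h -> adpglc_h + 2 pi_h", 0, 1000, "g_agp1 and g_agp2",
      "starch_sucrose", "2.7.7.27"),
    r("SS_h", "starch synthase", "adpglc_h -> starch_h + adp_h", 0, 1000,
      "g_ss1 or g_ss2", "starch_sucrose", "2.4.1.21"),
    r("GLYK_h", "glycerate kinase", "glyca_h + atp_h -> pga_h + adp_h",
      0, 1000, "g_glyk", "photorespiration", "2.7.1.31"),
    ## chloroplast C4-module and glycolytic branch
    r("NADPMDH_h", "NADP-malate dehydrogenase (malate valve)",
      "oaa_h + nadph_h -> mal_h + nadp_h", 0, 1000, "g_mdh_nadp1 or g_mdh_nadp2",
      "c4_cycle", "1.1.1.82"),
    r("NADPME_h", "NADP-malic enzyme",
      "mal_h + nadp_h -> pyr_h + co2_h + nadph_h", 0, 1000, "g_me_nadp",
      "c4_cycle", "1.1.1.40"),
    r("ENO_h", "plastid enolase (lumped with mutase)", "pga_h <=> pep_h",
      -1000, 1000, "g_eno_h", "respiration", "4.2.1.11"),
    r("PK_h", "plastid pyruvate kinase", "pep_h + adp_h -> pyr_h + atp_h",
      0, 1000, "g_pk_h", "respiration", "2.7.1.40"),
    r("FAS_h", "fatty acid synthesis (lumped, C16)",
      paste("8 pyr_h + 7 atp_h + 14 nadph_h ->",
            "fa_h + 8 co2_h + 7 adp_h + 7 pi_h + 14 nadp_h"),
      0, 1000, "g_accase and g_fas1", "fatty_acid", "2.3.1.85"),
    ## nitrogen assimilation
    r("NR_c", "nitrate reductase", "no3_c + nadh_c -> no2_c + nad_c",
      0, 1000, "g_nr1 or g_nr2", "nitrogen_assimilation", "1.7.1.1"),
    r("NiR_h", "ferredoxin-nitrite reductase (NADPH-lumped)",
      "no2_h + 3 nadph_h -> nh4_h + 3 nadp_h", 0, 1000, "g_nir",
      "nitrogen_assimilation", "1.7.7.1"),
    r("GS_h", "glutamine synthetase",
      "glu_h + nh4_h + atp_h -> gln_h + adp_h + pi_h", 0, 1000,
      "g_gs1 or g_gs2", "nitrogen_assimilation", "6.3.1.2"),
    r("GOGAT_h", "glutamate synthase (Fd, NADPH-lumped)",
      "gln_h + akg_h + nadph_h -> 2 glu_h + nadp_h", 0, 1000,
      "g_gogat_fd", "nitrogen_assimilation", "1.4.7.1"),
    ## photorespiratory glycolate route
    r("PGP_h", "phosphoglycolate phosphatase",
      "pglyc_h + h2o_h -> glyc_h + pi_h", 0, 1000, "g_pgp", "photorespiration",
      "3.1.3.18"),
    r("GOX_x", "glycolate oxidase", "glyc_x + o2_x -> glyox_x", 0, 1000,
      "g_gox1 or g_gox2", "photorespiration", "1.1.3.15"),
    r("GGAT_x", "glutamate:glyoxylate aminotransferase",
      "glyox_x + glu_x -> gly_x + akg_x", 0, 1000, "g_ggat", "photorespiration",
      "2.6.1.4"),
    r("SGAT_x", "serine:glyoxylate aminotransferase",
      "ser_x + glyox_x -> hpyr_x + gly_x", 0, 1000, "g_sgat", "photorespiration",
      "2.6.1.45"),
    r("HPR_x", "hydroxypyruvate reductase",
      "hpyr_x + nadh_x -> glyca_x + nad_x", 0, 1000, "g_hpr", "photorespiration",
      "1.1.1.29"),
    r("GDC_m", "glycine decarboxylase + SHMT (lumped)",
      "2 gly_m + nad_m -> ser_m + co2_m + nh4_m + nadh_m", 0, 1000,
      "g_gdc_p and g_gdc_h and g_shmt", "photorespiration", "1.4.4.2"),
    r("MDH_x", "peroxisomal malate dehydrogenase",
      "mal_x + nad_x -> oaa_x + nadh_x", 0, 1000, "g_mdh_x", "photorespiration",
      "1.1.1.37"),
    ## cytosolic glycolysis / sucrose synthesis / OPPP
    r("GAPDH_c", "glycolytic GAPDH + PGK (lumped)",
      "gap_c + nad_c + adp_c + pi_c -> pga_c + nadh_c + atp_c", 0, 1000,
      "g_gapc", "respiration", "1.2.1.12"),
    r("ENO_c", "enolase (lumped with mutase)", "pga_c <=> pep_c", -1000, 1000,
      "g_eno_c", "respiration", "4.2.1.11"),
    r("PK_c", "pyruvate kinase", "pep_c + adp_c -> pyr_c + atp_c", 0, 1000,
      "g_pk_c", "respiration", "2.7.1.40"),
    r("ALD_c", "cytosolic aldolase", "2 gap_c <=> fbp_c", -1000, 1000,
      "g_fba_c", "starch_sucrose", "4.1.2.13"),
    r("FBPase_c", "cytosolic fructose bisphosphatase",
      "fbp_c + h2o_c -> f6p_c + pi_c", 0, 1000, "g_fbp_c", "starch_sucrose",
      "3.1.3.11"),
    r("PGI_c", "phosphoglucose isomerase", "f6p_c <=> g6p_c", -1000, 1000,
      "g_pgi_c", "starch_sucrose", "5.3.1.9"),
    r("PGM_c", "phosphoglucomutase", "g6p_c <=> g1p_c", -1000, 1000,
      "g_pgm_c", "starch_sucrose", "5.4.2.2"),
    r("UGP_c", "NDP-glucose pyrophosphorylase (lumped)",
      "g1p_c + atp_c -> udpg_c + 2 pi_c", 0, 1000, "g_ugp", "starch_sucrose",
      "2.7.7.9"),
    r("SPS_c", "sucrose phosphate synthase",
      "udpg_c + f6p_c -> s6p_c + adp_c", 0, 1000, "g_sps1 or g_sps2",
      "starch_sucrose", "2.4.1.14"),
    r("SPP_c", "sucrose phosphate phosphatase",
      "s6p_c + h2o_c -> sucrose_c + pi_c", 0, 1000, "g_spp1 or g_spp2",
      "starch_sucrose", "3.1.3.24"),
    r("CESA_c", "cellulose synthase", "udpg_c -> cellulose_c + adp_c",
      0, 1000, "g_cesa1 and g_cesa2", "cell_wall", "2.4.1.12"),
    r("OPPP_c", "oxidative pentose phosphate pathway (G6PD+6PGD lumped)",
      "g6p_c + 2 nadp_c + h2o_c -> ru5p_c + co2_c + 2 nadph_c", 0, 1000,
      "g_g6pd1 or g_g6pd2", "pentose_phosphate", "1.1.1.49"),
    r("PPPn_c", "non-oxidative pentose phosphate (lumped)",
      "3 ru5p_c <=> 2 f6p_c + gap_c", -1000, 1000, "g_tkl_c", "pentose_phosphate",
      "2.2.1.1"),
    ## cytosolic C4-module and anaplerosis
    r("CA_c", "carbonic anhydrase", "co2_c + h2o_c <=> hco3_c", -1000, 1000,
      "g_ca1 or g_ca2", "c4_cycle", "4.2.1.1"),
    r("PEPC_c", "PEP carboxylase", "pep_c + hco3_c -> oaa_c + pi_c", 0, BIG,
      "g_pepc1 or g_pepc2 or g_pepc3", "c4_cycle", "4.1.1.31"),
    r("PEPCK_c", "PEP carboxykinase",
      "oaa_c + atp_c -> pep_c + co2_c + adp_c", 0, BIG,
      "g_pepck1 or g_pepck2", "c4_cycle", "4.1.1.49"),
    r("MDH_c", "cytosolic NAD-malate dehydrogenase",
      "oaa_c + nadh_c <=> mal_c + nad_c", -1000, 1000, "g_mdh_c1 or g_mdh_c2",
      "c4_cycle", "1.1.1.37"),
    r("AAT_c", "aspartate aminotransferase", "oaa_c + glu_c <=> asp_c + akg_c",
      -1000, 1000, "g_aat", "amino_acid", "2.6.1.1"),
    r("SAS_c", "sulfate assimilation + cysteine synthesis (lumped)",
      "so4_c + ser_c + atp_c + 4 nadph_c -> cys_c + adp_c + pi_c + 4 nadp_c",
      0, 1000, "g_aps and g_oastl", "amino_acid", "2.5.1.47"),
    r("PROT_c", "protein synthesis (residue mix)",
      paste("0.35 glu_c + 0.15 gln_c + 0.2 asp_c + 0.12 ser_c + 0.15 gly_c",
            "+ 0.03 cys_c + 4.3 atp_c -> protein_c + 4.3 adp_c + 4.3 pi_c"),
      0, 1000, NA_character_, "amino_acid"),
    r("NGAM_c", "maintenance ATPase", "atp_c + h2o_c -> adp_c + pi_c",
      7.5, 7.5, NA_character_, "maintenance"),
    ## mitochondrial respiration
    r("PDH_m", "pyruvate dehydrogenase",
      "pyr_m + coa_m + nad_m -> accoa_m + co2_m + nadh_m", 0, 1000,
      "g_pdh_e1 and g_pdh_e2", "respiration", "1.2.4.1"),
    r("CS_m", "citrate synthase", "accoa_m + oaa_m -> cit_m + coa_m", 0, 1000,
      "g_cs", "respiration", "2.3.3.1"),
    r("IDH_m", "isocitrate dehydrogenase (lumped with aconitase)",
      "cit_m + nad_m -> akg_m + co2_m + nadh_m", 0, 1000, "g_idh",
      "respiration", "1.1.1.41"),
    r("AKGDH_m", "2-oxoglutarate to malate (lumped TCA arm)",
      "akg_m + 2 nad_m + adp_m + pi_m -> mal_m + co2_m + atp_m + 2 nadh_m",
      0, 1000, "g_akgdh and g_scs", "respiration", "1.2.4.2"),
    r("MDH_m", "mitochondrial malate dehydrogenase",
      "mal_m + nad_m <=> oaa_m + nadh_m", -1000, 1000,
      "g_mdh_m1 or g_mdh_m2", "respiration", "1.1.1.37"),
    r("NADME_m", "NAD-malic enzyme",
      "mal_m + nad_m -> pyr_m + co2_m + nadh_m", 0, 1000, "g_me_nad",
      "c4_cycle", "1.1.1.38"),
    r("ETC_m", "mitochondrial electron transport chain (lumped)",
      "2 nadh_m + o2_m + 5 adp_m + 5 pi_m -> 2 nad_m + 5 atp_m", 0, 1000,
      "g_cox and g_atps_m", "respiration", "1.9.3.1")
  )
}

#' Build the synthetic C3-leaf core model
#'
#' Constructs the curated four-compartment leaf network: lumped
#' photosystems with linear and cyclic electron flow, RuBisCO as separate
#' carboxylase/oxygenase reactions, the full glycolate route through
#' peroxisome and mitochondrion with GDC releasing CO2 and ammonium,
#' GS/GOGAT refixation, glycolysis, TCA cycle, mitochondrial electron
#' transport, cytosolic OPPP, the PEPC/PEPCK/malic-enzyme module with
#' carbonic anhydrase, malate/oxaloacetate and ATP/ADP shuttles, starch,
#' sucrose and cell-wall synthesis, and a biomass reaction assembled from
#' the configured mass fractions.
#'
#' The photon budget is then calibrated: the model is solved once with the
#' CO2 uptake capped at `net_photosynthesis` and photons free, and the
#' photon influx is pinned at the canonical (minimum-total-flux) photon
#' demand of that optimum. This makes light supply exactly consistent with
#' the configured assimilation rate; the Vc/Vo ratio constraint
#' (`vc_vo_default`) is attached before calibration. Passing a numeric
#' `lue` in the configuration skips calibration and pins the influx at
#' `net_photosynthesis / lue`.
#'
#' @param config a [fixture_config()].
#' @param calibrate run the photon calibration (disabled internally for
#'   structural tests).
#' @return a validated [cbm_model()] with growth > 0; annotations carry
#'   `key_reactions`, `shuttles`, the configuration and the calibrated
#'   photon budget.
#' @export
build_fixture_leaf_model <- function(config = fixture_config(),
                                     calibrate = TRUE) {
  stopifnot(inherits(config, "fixture_config"))
  comps <- data.frame(
    id = c("c", "h", "m", "x", "e"),
    name = c("cytosol", "chloroplast", "mitochondrion", "peroxisome",
             "external"))
  mets <- fixture_metabolites()
  rxns <- fixture_reactions()

  ## biomass equation from mass fractions
  fr <- config$biomass_fractions
  coefs <- fr / fixture_mw[names(fr)] * 1000   # mmol per gDW
  gam <- 10                                    # growth-associated ATP, mmol/g
  prec <- c(carbohydrate = "starch_h", protein = "protein_c",
            fiber = "cellulose_c", lipid = "fa_h")
  eq <- sprintf("%s + %s atp_c -> biomass_c + %s adp_c + %s pi_c",
                paste(sprintf("%s %s", fmt_num(coefs), prec[names(fr)]),
                      collapse = " + "),
                fmt_num(gam), fmt_num(gam), fmt_num(gam))
  rxns <- rbind(rxns, data.frame(
    id = "BIOMASS", name = "leaf biomass synthesis", equation = eq,
    lb = 0, ub = 1000, gpr = NA_character_, pathway = "biomass",
    ec = NA_character_, stringsAsFactors = FALSE))

  ## derived formulas keep every internal reaction element-balanced
  fcount <- function(id, el) {
    f <- parse_formula(mets$formula[match(id, mets$id)])
    v <- f[el]; if (is.na(v)) 0 else as.numeric(v)
  }
  prot_mix <- c(glu_c = 0.35, gln_c = 0.15, asp_c = 0.2, ser_c = 0.12,
                gly_c = 0.15, cys_c = 0.03)
  pf <- vapply(c("C", "N", "S"), function(el)
    sum(prot_mix * vapply(names(prot_mix), fcount, numeric(1), el = el)),
    numeric(1))
  mets$formula[mets$id == "protein_c"] <-
    sprintf("C%sN%sS%s", fmt_num(pf["C"]), fmt_num(pf["N"]), fmt_num(pf["S"]))
  bf <- vapply(c("C", "N", "S"), function(el)
    sum(coefs * vapply(prec[names(fr)], fcount, numeric(1), el = el)),
    numeric(1))
  mets$formula[mets$id == "biomass_c"] <-
    sprintf("C%sN%sS%s", fmt_num(bf["C"]), fmt_num(bf["N"]), fmt_num(bf["S"]))

  st_all <- NULL
  for (i in seq_len(nrow(rxns))) {
    pe <- parse_equation(rxns$equation[i], rxns$id[i])
    st_all <- rbind(st_all, cbind(reaction = rxns$id[i], pe$stoich))
  }
  rxns$lb[rxns$id == "NGAM_c"] <- config$maintenance_atp
  rxns$ub[rxns$id == "NGAM_c"] <- config$maintenance_atp

  model <- cbm_model(
    id = "leaf_core",
    compartments = comps, metabolites = mets,
    reactions = rxns[, c("id", "name", "lb", "ub", "gpr", "pathway", "ec")],
    stoich = st_all,
    objective = c(BIOMASS = 1),
    annotations = list(
      config = unclass(config),
      key_reactions = list(growth = "BIOMASS", co2_exchange = "EX_co2",
                           photon_exchange = "EX_photon",
                           vc = "RBC_carb", vo = "RBC_oxy", pepc = "PEPC_c",
                           pepck = "PEPCK_c", oppp = "OPPP_c",
                           sucrose_export = "EX_sucrose"),
      shuttles = list(
        atp_chl_to_cyt = "AAC_hc",      # positive flux = ATP into cytosol
        atp_mit_to_cyt = "AAC_mc",
        nadh_chl_to_cyt = "T_mal_hc",   # malate/OAA shuttle, positive = h->c
        nadh_mit_to_cyt = "T_mal_mc",
        nadh_cyt_to_perox = "T_mal_cx")))
  model <- apply_ratio_constraint(
    model, ratio_constraint("RBC_carb", "RBC_oxy", config$vc_vo_default))

  if (!calibrate) return(model)

  if (is.null(config$lue)) {
    ## photon calibration: CO2 capped at P_N, photons free, take the
    ## canonical photon demand of the optimum
    cal <- model
    cal <- set_uptake_bound(cal, "EX_co2", config$net_photosynthesis)
    sol <- solve_fba(cal)
    if (!identical(sol$status, "optimal"))
      stop("fixture calibration solve failed")
    can <- canonicalize(cal, sol)
    photon_budget <- -can$fluxes[["EX_photon"]]
  } else {
    photon_budget <- config$net_photosynthesis / config$lue
  }
  model <- set_uptake_bound(model, "EX_photon", photon_budget, pin = TRUE)
  model$annotations$photon_budget <- photon_budget
  model
}

#' Path of the packaged leaf core model
#' @return path to the TSV model shipped in `inst/extdata`.
#' @export
leaf_core_model_path <- function() {
  system.file("extdata", "leaf_core_model.tsv", package = "leafcbm",
              mustWork = TRUE)
}

#' Load the packaged leaf core model
#'
#' Reads the shipped TSV snapshot of [build_fixture_leaf_model()] with the
#' default configuration (including the calibrated photon pin) and
#' re-attaches the Vc/Vo ratio constraint and annotation metadata.
#'
#' @return a [cbm_model()].
#' @export
leaf_core_model <- function() {
  model <- load_model(leaf_core_model_path(), format = "tsv")
  cfg <- fixture_config()
  tmpl <- build_fixture_leaf_model(cfg, calibrate = FALSE)
  model$annotations <- tmpl$annotations
  model$annotations$photon_budget <- -model$reactions$lb[
    match("EX_photon", model$reactions$id)]
  apply_ratio_constraint(
    model, ratio_constraint("RBC_carb", "RBC_oxy", cfg$vc_vo_default))
}
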