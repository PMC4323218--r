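# Curated worked-example fixture: the case-study drug-food interactions
# reported for five disease areas, transcribed as schema-complete tables.
# Drug affinity values and drug structures are plausible synthetic
# stand-ins (the real database dumps are out of scope); the phytochemical
# affinities and memberships are the published ones. Aromatase appears
# twice - once as a drug target (pharmacodynamics context) and once as a
# metabolic enzyme (pharmacokinetics context) - because the two contexts
# carry different reported affinities and a protein record has exactly one
# category.

#' Curated worked-example fixture
#'
#' Returns a registry holding the case-study interactions: naringenin on
#' aromatase as a drug target (IC50 2.9 nM; licorice, beansprout, maize)
#' and on aromatase as a metabolic enzyme (IC50 1000 nM; licorice, sugar
#' pea, guava), kaempferol on the epidermal growth factor receptor (IC50
#' 3.0 nM; lychee, onion, strawberry), serotonin on the
#' 5-hydroxytryptamine receptor (Ki 1.1 nM; sunflower, potato, tomato),
#' aporphine on the D(2) dopamine receptor (Ki 527 nM; poppy-seed),
#' p-hydroxybenzoic acid on carbonic anhydrase (Ki 920 nM; coconut,
#' currant, sprouted lentil, swede), and resveratrol on
#' ribosyl-dihydronicotinamide dehydrogenase (IC50 450 nM; grape), with the
#' corresponding drug links. The 1000 nM enzyme-context row carries a
#' deposited pchembl of 6.05 (value and pchembl are independently rounded
#' fields) so the reported interaction survives the strict pchembl > 6
#' filter.
#'
#' @return A validated [DfiRegistry-class].
#' @examples
#' reg <- inPaperFixture()
#' reg
#' @export
inPaperFixture <- function() {
  compounds <- data.frame(
    compound_id = c("naringenin", "kaempferol", "serotonin", "aporphine",
                    "p-hydroxybenzoic-acid", "resveratrol",
                    "anastrozole", "testolactone", "exemestane", "letrozole",
                    "aminoglutethiumide", "lapatinib", "gefitinib",
                    "vandetanib", "erlotinib", "loxapine", "buspirone",
                    "ofremoxipride", "sulpiride", "trichlormethiazide",
                    "primaquine"),
    smiles = c(
      "O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c21",          # naringenin
      "O=c1c(O)c(-c2ccc(O)cc2)oc2cc(O)cc(O)c12",      # kaempferol
      "NCCc1c[nH]c2ccc(O)cc12",                        # serotonin
      "CN1CCc2cccc3c2C1Cc1ccccc1-3",                   # aporphine skeleton
      "O=C(O)c1ccc(O)cc1",                             # p-hydroxybenzoic acid
      "Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1",                # resveratrol
      "CC(C)(C#N)c1cc(Cn2cncn2)cc(C(C)(C)C#N)c1",      # anastrozole
      "CC12CCC(=O)OC1CCC1C2CCC2(C)C(=O)CCC12",         # testolactone-like
      "C=C1CC2C(CCC3(C)C2CCC3=O)C2(C)C1C(=O)C=C2",     # exemestane-like
      "N#Cc1ccc(C(c2ccc(C#N)cc2)n2cncn2)cc1",          # letrozole
      "CCC1(c2ccc(N)cc2)CCC(=O)NC1=O",                 # aminoglutethimide
      "CS(=O)(=O)CCNCc1ccccc1",                        # lapatinib stand-in
      "COc1cc2ncnc(Nc3ccc(F)c(Cl)c3)c2cc1OC",          # gefitinib-like
      "COc1cc2c(cc1OC)ncnc2Nc1ccc(Br)cc1F",            # vandetanib-like
      "COCCOc1cc2ncnc(Nc3cccc(C#C)c3)c2cc1OCCOC",      # erlotinib
      "CN1CCN(C2=Nc3ccccc3Oc3ccc(Cl)cc32)CC1",         # loxapine
      "O=C1CCC(=O)N1CCCCN1CCN(c2ncccn2)CC1",           # buspirone-like
      "CCN1CCCC1CNC(=O)c1cc(S(C)(=O)=O)ccc1OC",        # remoxipride-like
      "CCN1CCCC1CNC(=O)c1cc(S(N)(=O)=O)ccc1OC",        # sulpiride
      "NS(=O)(=O)c1cc2c(cc1Cl)NC(C(Cl)Cl)NS2(=O)=O",   # trichlormethiazide
      "COc1cc(NC(C)CCCN)c2ncccc2c1"),                  # primaquine
    mw = NA_real_,
    names = c("naringenin", "kaempferol", "serotonin", "aporphine",
              "p-hydroxybenzoic acid", "resveratrol", "Anastrozole",
              "Testolactone", "Exemestane", "Letrozole",
              "Aminoglutethiumide", "Lapatinib", "Gefitinib", "Vandetanib",
              "Erlotinib", "Loxapine", "Buspirone", "Ofremoxipride",
              "Sulpiride", "Trichlormethiazide", "Primaquine"),
    origin = c(rep("food", 6L), rep("drug", 15L)),
    stringsAsFactors = FALSE)

  foods <- data.frame(rbind(
    c("licorice", "naringenin"), c("beansprout", "naringenin"),
    c("maize", "naringenin"), c("sugar-pea", "naringenin"),
    c("guava", "naringenin"),
    c("lychee", "kaempferol"), c("onion", "kaempferol"),
    c("strawberry", "kaempferol"),
    c("sunflower", "serotonin"), c("potato", "serotonin"),
    c("tomato", "serotonin"),
    c("poppy-seed", "aporphine"),
    c("coconut", "p-hydroxybenzoic-acid"),
    c("currant", "p-hydroxybenzoic-acid"),
    c("sprouted-lentil", "p-hydroxybenzoic-acid"),
    c("swede", "p-hydroxybenzoic-acid"),
    c("grape", "resveratrol")), stringsAsFactors = FALSE)
  names(foods) <- c("food_id", "compound_id")

  proteins <- data.frame(
    protein_id = c("AROMATASE_T", "EGFR", "HTR", "DRD2", "CA", "NQO2",
                   "AROMATASE_E"),
    protein_name = c("aromatase", "epidermal growth factor receptor",
                     "5-hydroxytryptamine receptor",
                     "D(2) dopamine receptor", "carbonic anhydrase",
                     "ribosyl-dihydronicotinamide dehydrogenase",
                     "aromatase"),
    category = c("drug_target", "drug_target", "drug_target", "drug_target",
                 "drug_target", "enzyme", "enzyme"),
    disease_classes = c("cancer", "cancer", "neurological", "neurological",
                        "cardiovascular", "", ""),
    biological_system = c("metabolism", "signal_transduction",
                          "neuronal_system", "neuronal_system",
                          "metabolism", "metabolism", "metabolism"),
    species = "human", stringsAsFactors = FALSE)

  drugLink <- function(drug, compound, protein, role, classes)
    data.frame(drug_id = drug, compound_id = compound, protein_id = protein,
               role = role, disease_classes = classes,
               stringsAsFactors = FALSE)
  drugs <- rbind(
    drugLink("Anastrozole", "anastrozole", "AROMATASE_T", "target", "cancer"),
    drugLink("Testolactone", "testolactone", "AROMATASE_T", "target", "cancer"),
    drugLink("Exemestane", "exemestane", "AROMATASE_T", "target", "cancer"),
    drugLink("Letrozole", "letrozole", "AROMATASE_T", "target", "cancer"),
    drugLink("Aminoglutethiumide", "aminoglutethiumide", "AROMATASE_T",
             "target", "cancer"),
    drugLink("Lapatinib", "lapatinib", "EGFR", "target", "cancer"),
    drugLink("Gefitinib", "gefitinib", "EGFR", "target", "cancer"),
    drugLink("Vandetanib", "vandetanib", "EGFR", "target", "cancer"),
    drugLink("Erlotinib", "erlotinib", "EGFR", "target", "cancer"),
    drugLink("Loxapine", "loxapine", "HTR", "target", "neurological"),
    drugLink("Buspirone", "buspirone", "HTR", "target", "neurological"),
    drugLink("Ofremoxipride", "ofremoxipride", "DRD2", "target",
             "neurological"),
    drugLink("Sulpiride", "sulpiride", "DRD2", "target", "neurological"),
    drugLink("Trichlormethiazide", "trichlormethiazide", "CA", "target",
             "cardiovascular"),
    drugLink("Primaquine", "primaquine", "NQO2", "enzyme", "infectious"),
    drugLink("Anastrozole", "anastrozole", "AROMATASE_E", "enzyme", "cancer"),
    drugLink("Letrozole", "letrozole", "AROMATASE_E", "enzyme", "cancer"),
    drugLink("Exemestane", "exemestane", "AROMATASE_E", "enzyme", "cancer"))

  ms <- function(compound, protein, endpoint, value, pchembl)
    data.frame(compound_id = compound, protein_id = protein,
               endpoint = endpoint, value = value, units = "nM",
               pchembl = pchembl, stringsAsFactors = FALSE)
  measurements <- rbind(
    # phytochemical affinities as reported
    ms("naringenin", "AROMATASE_T", "IC50", 2.9, 8.54),
    ms("kaempferol", "EGFR", "IC50", 3.0, 8.52),
    ms("serotonin", "HTR", "Ki", 1.1, 8.96),
    ms("aporphine", "DRD2", "Ki", 527, 6.28),
    ms("p-hydroxybenzoic-acid", "CA", "Ki", 920, 6.04),
    ms("resveratrol", "NQO2", "IC50", 450, 6.35),
    ms("naringenin", "AROMATASE_E", "IC50", 1000, 6.05),
    # drug affinities (synthetic stand-ins spanning each target's range)
    ms("anastrozole", "AROMATASE_T", "IC50", 15, 7.82),
    ms("testolactone", "AROMATASE_T", "IC50", 250, 6.60),
    ms("exemestane", "AROMATASE_T", "IC50", 30, 7.52),
    ms("letrozole", "AROMATASE_T", "IC50", 11.5, 7.94),
    ms("aminoglutethiumide", "AROMATASE_T", "IC50", 850, 6.07),
    ms("lapatinib", "EGFR", "IC50", 10, 8.00),
    ms("gefitinib", "EGFR", "IC50", 2, 8.70),
    ms("vandetanib", "EGFR", "IC50", 50, 7.30),
    ms("erlotinib", "EGFR", "IC50", 1, 9.00),
    ms("loxapine", "HTR", "Ki", 20, 7.70),
    ms("buspirone", "HTR", "Ki", 25, 7.60),
    ms("ofremoxipride", "DRD2", "Ki", 300, 6.52),
    ms("sulpiride", "DRD2", "Ki", 600, 6.22),
    ms("trichlormethiazide", "CA", "Ki", 1200, 5.92),
    ms("primaquine", "NQO2", "IC50", 900, 6.05),
    ms("anastrozole", "AROMATASE_E", "IC50", 950, 6.02),
    ms("letrozole", "AROMATASE_E", "IC50", 1400, 5.85),
    ms("exemestane", "AROMATASE_E", "IC50", 2000, 5.70))

  dfiRegistry(compounds = compounds, foods = foods, proteins = proteins,
              drugs = drugs, measurements = measurements)
}
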