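# In-code fixtures: tiny hand-built surveys and the two-year survey
# composition encoded from its published totals.

toyTraits <- function() {
  data.frame(
    species_id = c("a1", "a2", "b1", "c1", "n1"),
    diet = c("generalist", "specialist", "generalist", "parasitic",
             "generalist"),
    native = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    genus = c("Andrena", "Andrena", "Bombus", "Coelioxys", "Apis"),
    stringsAsFactors = FALSE)
}

toyRecords <- function() {
  data.frame(
    plot_id = c("P1", "P1", "P1", "P1", "P2", "P2", "P2", "P1", "P2", "P1"),
    treatment = c(rep("reserve", 4), rep("fragment", 3), "reserve",
                  "fragment", "reserve"),
    year = 2011L,
    julian_date = c(100L, 100L, 100L, 150L, 100L, 100L, 150L, 150L, 150L,
                    100L),
    method = c(rep("bowl", 7), "net", "bowl", "bowl"),
    species_id = c("a1", "a2", "b1", "a1", "a1", "b1", "a2", "b1", "c1",
                   "n1"),
    count = c(2L, 3L, 1L, 4L, 5L, 2L, 1L, 3L, 2L, 6L),
    id_level = c(rep("species", 9), "species"),
    stringsAsFactors = FALSE)
}

# Survey composition with the published totals: 11,549 native specimens
# from bowls (9,421 over 168 species) and nets (2,128 over 179 species),
# 235 species in total (112 caught by both methods).
methodCompositionRecords <- function() {
  bowlSp <- paste0("s", 1:168)
  netSp <- paste0("s", c(1:112, 169:235))
  mk <- function(sp, total, method) {
    n <- length(sp)
    data.frame(plot_id = "P1", treatment = "reserve", year = 2011L,
               julian_date = 120L, method = method, species_id = sp,
               count = c(rep(1L, n - 1), total - (n - 1L)),
               id_level = "species", stringsAsFactors = FALSE)
  }
  rbind(mk(bowlSp, 9421L, "bowl"), mk(netSp, 2128L, "net"))
}

# Identification-level totals over all 12,036 specimens: 11,449 to species,
# 424 to morphospecies, 163 left at genus.
idLevelRecords <- function() {
  data.frame(plot_id = "P1", treatment = "reserve", year = 2011L,
             julian_date = 120L, method = "bowl",
             species_id = c("s1", "m1", "g1"),
             count = c(11449L, 424L, 163L),
             id_level = c("species", "morphospecies", "genus_only"),
             stringsAsFactors = FALSE)
}

# Bowl-trap specimens: 9,421 in total of which 78 are genus-level only.
bowlIdRecords <- function() {
  data.frame(plot_id = "P1", treatment = "reserve", year = 2011L,
             julian_date = 120L, method = "bowl",
             species_id = c("s1", "g1"),
             count = c(9343L, 78L),
             id_level = c("species", "genus_only"), stringsAsFactors = FALSE)
}

# records -> AbundanceMatrix with default filters off except methods
toyMatrix <- function(records = toyRecords(), traits = toyTraits(), ...) {
  abundanceMatrix(filterRecords(records, dropNonnative = TRUE,
                                traits = traits, ...), traits)
}

# quick pipeline fragment used by several simulation-based tests
simToMatrix <- function(cfg, year = 2011L) {
  sim <- simulateSurvey(cfg, year = year)
  fr <- filterRecords(sim$records, traits = sim$traits)
  list(am = abundanceMatrix(fr, sim$traits), sim = sim)
}
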