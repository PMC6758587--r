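# Shared simulation fixtures, built once per test run.  Scale and
# coverages follow the package's default desk-scale study conditions.

.fx <- new.env(parent = emptyenv())

testFixture <- function(scale = 50000, seed = 1) {
    key <- sprintf("fx_%d_%d", scale, seed)
    if (is.null(.fx[[key]]))
        .fx[[key]] <- buildFixtureKaryotype(scale, seed)
    .fx[[key]]
}

matePairLib <- function(coverage = 30)
    libraryModel(5000, 300, 150, coverage = coverage)

pairedEndLib <- function(coverage = 20)
    libraryModel(500, 50, 150, coverage = coverage)

accHomAlt <- function(name = "C4like")
    accessionSpec(name, "burmannica_like",
                  c(`2/8` = "hom_alt", `1/9` = "hom_alt"))

accHomRef <- function(name = "DHPlike")
    accessionSpec(name, "standard_like",
                  c(`2/8` = "hom_ref", `1/9` = "hom_ref"))

accHet28 <- function(name = "Mananglike")
    accessionSpec(name, "cultivated",
                  c(`2/8` = "het", `1/9` = "hom_ref"))

# cached mate-pair read sets against the reference template
testPairs <- function(which = c("hom_alt", "hom_ref", "het"),
                      seed = 5, coverage = 30) {
    which <- match.arg(which)
    key <- sprintf("pr_%s_%d_%d", which, seed, coverage)
    if (is.null(.fx[[key]])) {
        acc <- switch(which, hom_alt = accHomAlt(), hom_ref = accHomRef(),
                      het = accHet28())
        .fx[[key]] <- simulateReadPairs(testFixture(), acc,
                                        matePairLib(coverage), seed = seed)
    }
    .fx[[key]]
}

# expected SSJ call for a simulated genotype: reference chromosomes 1/9
# carry no signature junctions, so their homozygotes are undetectable
# and 1/9 heterozygotes are indistinguishable from hom_alt
expectedSSJCall <- function(genotype, group) {
    if (group == "1/9")
        switch(genotype, hom_alt = "hom_alt", het = "hom_alt",
               hom_ref = "undetermined")
    else genotype
}
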