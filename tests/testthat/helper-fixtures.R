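# Fixtures built in code; no binary data.

# The early-hominin record: four fossiliferous places in Africa.
# Sahelanthropus (FAD, dated 6.5-7.5 Ma), Orrorin (6.0-5.7), and two
# Ardipithecus horizons (5.8-5.2 and 4.4).
hominin_occurrences <- function() {
  occurrences(
    taxon_id = c("Sahelanthropus_tchadensis", "Orrorin_tugenensis",
                 "Ardipithecus_kadabba", "Ardipithecus_ramidus"),
    lineage_id = "hominin",
    locality_id = c("Toros-Menalla", "Lukeino", "Asa_Koma", "Aramis"),
    horizon_id = c("h1", "h2", "h3", "h4"),
    age_older_ma = c(7.5, 6.0, 5.8, 4.4),
    age_younger_ma = c(6.5, 5.7, 5.2, 4.4),
    region = "Africa",
    apomorphy = TRUE
  )
}

hominin_record <- function(extant = TRUE) {
  lineage_record(hominin_occurrences(), extant = extant)
}

read_tree_text <- function(text) {
  ultrametric_topology(ape::read.tree(text = text))
}

# quiet wrappers: package logging goes to stderr via message()
quietly <- function(expr) suppressMessages(suppressWarnings(expr))
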