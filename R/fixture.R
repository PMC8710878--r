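# Synthetic 33-species time-calibrated tree, assembled by successive
# calibrated grafts from a two-tip seed. Node ages are rough TimeTree-style
# divergence times in Myr; the compiled tree is a stand-in for a published
# supertree (which is not redistributable), built so that the two splits
# with explicit calibrations — the North Island / South Island robin
# divergence at 3 Myr and the dog/wolf divergence at 15,000 years
# (0.015 Myr) — are exact.

# each row: existing tip, new tip, divergence age (Myr)
GRAFT_TABLE_33 <- rbind(
  # birds
  c("North_Island_robin", "pigeon",               "98"),
  c("pigeon",             "domestic_chicken",     "85"),
  c("North_Island_robin", "kea",                  "80"),
  c("kea",                "African_grey_parrot",  "60"),
  c("North_Island_robin", "zebra_finch",          "45"),
  c("North_Island_robin", "jackdaw",              "35"),
  c("jackdaw",            "New_Caledonian_crow",  "15"),
  c("New_Caledonian_crow", "carrion_crow",        "5"),
  c("North_Island_robin", "South_Island_robin",   "3"),
  # mammals
  c("dog",                "African_elephant",     "100"),
  c("dog",                "ring_tailed_lemur",    "96"),
  c("ring_tailed_lemur",  "spider_monkey",        "74"),
  c("spider_monkey",      "rhesus_macaque",       "43"),
  c("spider_monkey",      "capuchin_monkey",      "26"),
  c("capuchin_monkey",    "squirrel_monkey",      "14"),
  c("rhesus_macaque",     "chimpanzee",           "29"),
  c("chimpanzee",         "gibbon",               "20"),
  c("chimpanzee",         "orangutan",            "16"),
  c("chimpanzee",         "gorilla",              "9"),
  c("chimpanzee",         "bonobo",               "2"),
  c("rhesus_macaque",     "hamadryas_baboon",     "12"),
  c("hamadryas_baboon",   "olive_baboon",         "4"),
  c("rhesus_macaque",     "long_tailed_macaque",  "5"),
  c("dog",                "horse",                "78"),
  c("horse",              "cattle",               "76"),
  c("cattle",             "domestic_pig",         "62"),
  c("cattle",             "bottlenose_dolphin",   "56"),
  c("dog",                "cat",                  "54"),
  c("dog",                "South_American_sea_lion", "45"),
  c("dog",                "coyote",               "4"),
  c("dog",                "wolf",                 "0.015")
)

#' Synthetic 33-species time-calibrated tree
#'
#' Builds an ultrametric tree over 33 bird and mammal species — 10 birds,
#' 10 nonprimate mammals and 13 primates — by grafting calibrated splits
#' onto a two-tip bird/mammal seed (root at 320 Myr). Divergence times are
#' approximate literature values; the tree is a synthetic stand-in with the
#' right structural footprint for a comparative quantity-discrimination
#' analysis, not a published phylogeny. Two calibrations are exact by
#' construction: the North Island / South Island robin split at 3 Myr and
#' the dog/wolf split at 0.015 Myr (15,000 years).
#'
#' @return an ultrametric \code{phylo} with 33 tips, ages in Myr.
#' @export
example_timetree <- function() {
  tree <- load_tree("(North_Island_robin:320,dog:320);")
  for (i in seq_len(nrow(GRAFT_TABLE_33))) {
    tree <- graft_split(tree, GRAFT_TABLE_33[i, 1], GRAFT_TABLE_33[i, 2],
                        as.numeric(GRAFT_TABLE_33[i, 3]))
  }
  tree
}
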