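#!/usr/bin/env Rscript
# Community structure of the oyster-reef survey: per-transect diversity of
# the plankton assemblages, McNaughton dominance, and the reef-fauna
# checklist summary. Writes tables under results/.

library(reefweb)
dir.create("results", showWarnings = FALSE)

zoo <- plankton_fixture("zooplankton")
phy <- plankton_fixture("phytoplankton")

div <- rbind(cbind(assemblage = "zooplankton", stratified_summary(zoo)),
             cbind(assemblage = "phytoplankton", stratified_summary(phy)))
write.csv(div, "results/diversity_transects.csv", row.names = FALSE)

message("Plankton diversity by transect:")
print(div[, c("assemblage", "stratum", "S", "N", "H", "d", "J")], digits = 3)
message("Zooplankton peak diversity on transect B (H' = ",
        round(div$H[div$assemblage == "zooplankton" & div$stratum == "B"], 2),
        ", d = ",
        round(div$d[div$assemblage == "zooplankton" & div$stratum == "B"], 2),
        "); phytoplankton richness peaks on transect C (S = ",
        div$S[div$assemblage == "phytoplankton" & div$stratum == "C"], ").")

dom_z <- mcnaughton_dominance(zoo)
dom_p <- mcnaughton_dominance(phy)
write.csv(dom_z, "results/dominance_zooplankton.csv", row.names = FALSE)
write.csv(dom_p, "results/dominance_phytoplankton.csv", row.names = FALSE)
message("Dominant (Y > 0.02) zooplankton: ",
        paste(dom_z$species[dom_z$dominant], collapse = ", "))
message("Dominant phytoplankton: ",
        paste(dom_p$species[dom_p$dominant], collapse = ", "))

ck <- reef_checklist_fixture()
summ <- aggregate(species ~ phylum, ck, length)
names(summ)[2] <- "n_species"
write.csv(summ[order(-summ$n_species), ], "results/checklist_summary.csv",
          row.names = FALSE)
message(nrow(ck), " reef-dwelling species across ",
        length(unique(ck$phylum)), " phyla; Mollusca holds ",
        summ$n_species[summ$phylum == "Mollusca"], " of them.")
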