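#!/usr/bin/env Rscript
# Fermentation behavior: product envelopes at 95% of optimal growth,
# boundary carbon accounting, growth efficiency per C-mmol, and a
# supplementation scan ranking nutrients by product gains.

suppressMessages(library(bfgem))
dir.create("results", showWarnings = FALSE)

model <- toy_fermenter()
medium <- toy_medium(10)
products <- c("EX_prod1_e", "EX_prod2_e")

env <- fermentation_envelope(model, medium, products,
                             growth_fraction = 0.95, co2 = NULL)
message("product envelope (rows = maximized product):")
print(round(as.matrix(env), 3))
message(sprintf("growth window: [%.4f, %.4f] 1/h",
                attr(env, "growth_window")[1], attr(env, "growth_window")[2]))

sol <- fba(apply_medium(model, medium))
cb <- carbon_balance(model, sol)
message(sprintf(
  "carbon: %.1f C-mmol/gDW/h in, %.1f out as products (%.1f%%), %.1f to biomass",
  cb$c_in, cb$c_out_products, 100 * cb$fraction_to_products, cb$c_in_biomass))

minerals <- medium_spec(c(EX_nh3_e = 1000, EX_h2o_e = 1000))
eff <- growth_efficiency(model, c("EX_sub_e", "EX_ser_e"), minerals,
                         total_c_flux = 120)
print(eff)

scan <- supplementation_scan(model, medium, products,
                             supplements = c("EX_sub_e", "EX_ser_e",
                                             "EX_aa2_e", "EX_prod1_e",
                                             "EX_prod2_e"))
message("supplement ranking per product:")
print(attr(scan, "ranking"))
message("product-1 : product-2 ratio by supplement:")
print(round(attr(scan, "ratios"), 3))

write.table(cbind(maximized = rownames(env), round(env, 6)),
            "results/envelope.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(eff, "results/growth_efficiency.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(scan, "results/supplement_scan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/envelope.tsv, growth_efficiency.tsv, supplement_scan.tsv")
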