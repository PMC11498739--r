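#!/usr/bin/env Rscript
# Monte-Carlo reverse dosimetry on synthetic worker series.
#
# Builds an applicator-style series (serial voids over three work days,
# hourly oral exposure 08:00-15:00 at exactly the AOEL-equivalent
# 1400 pmol/kg bw/d, volunteer-6 kinetics as ground truth) and a
# field-worker series (four 24-h collections, five daily hand-to-mouth
# contacts), reconstructs absorbed doses under the candidate exposure
# scenarios, and writes daily-dose and AOEL-exceedance reports.
#
# Findings: the oral scenario reproduces the series within the 5%
# acceptance deviation and recovers the known daily dose within ~10%;
# the dermal scenario cannot approach the acceptance deviation (skin
# penetration at the volunteer-fitted rates is far too slow), which is
# the mechanistic reason the study attributes applicator exposure to
# inadvertent ingestion. Exceedance probabilities near 50% are expected
# since the true dose sits exactly at the AOEL.

suppressPackageStartupMessages(library(cyhalotk))
dir.create("results", showWarnings = FALSE)
cfg <- lct_config(seed = 1L, n_accept = 200L)
log_config(cfg)

ens_oral <- fixture_ensembles("table2")
ens_comb <- fixture_ensembles("combined")

## applicator: hourly oral bins over the work hours
work_hours <- as.numeric(outer(8:15, 24 * (0:2), "+"))
scen_oral <- scenario_hourly("oral", work_hours)
app <- generate_worker_study(
  rep(lct_constants()$aoel_pmol_kg_d / 8, length(work_hours)),
  scen_oral, design_applicator(3), fixture_params(6, dermal = FALSE),
  noise = lct_noise(cv_urine = 0.1, loq_urine = 1, seed = 21),
  subject = "A1-synth")

rec <- reconstruct(app$series, scen_oral, ens_oral,
                   n_accept = cfg$n_accept, max_R = cfg$max_R,
                   seed = cfg$seed)
print(rec)
rep_app <- exceedance(rec, threshold = lct_constants()$aoel_pmol_kg_d,
                      seed = cfg$seed)
write_exceedance_csv(rep_app, "results/applicator_exceedance.csv")
print(rep_app, digits = 3)

## route contrast on the same series
r_oral <- best_attainable_R(app$series, scen_oral, ens_oral,
                            n_try = 50, seed = 2)
r_dermal <- best_attainable_R(app$series,
                              scenario_hourly("dermal", work_hours),
                              ens_comb, n_try = 50, seed = 2)
r_inh <- best_attainable_R(app$series,
                           scenario_hourly("inhalation", work_hours),
                           ens_oral, n_try = 50, seed = 2)
routes <- data.frame(route = c("oral", "dermal", "inhalation"),
                     best_R = c(r_oral, r_dermal, r_inh),
                     passes_5pct = c(r_oral, r_dermal, r_inh) <= cfg$max_R)
write.csv(routes, "results/route_contrast.csv", row.names = FALSE)
print(routes, digits = 3)

## field worker: five daily oral contacts, 24-h collections
scen_fw <- scenario_daily5("oral", n_days = 4)
fw_doses <- rep(200 / 5, length(scen_fw$bin_times))  # 200 pmol/kg bw/d
fw <- generate_worker_study(fw_doses, scen_fw, design_fieldworker(4),
                            fixture_params(6, dermal = FALSE),
                            noise = lct_noise(cv_urine = 0.1,
                                              loq_urine = 1, seed = 22),
                            subject = "F1-synth")
rec_fw <- reconstruct(fw$series, scen_fw, ens_oral,
                      n_accept = cfg$n_accept, max_R = cfg$max_R,
                      seed = cfg$seed)
rep_fw <- exceedance(rec_fw, threshold = lct_constants()$aoel_pmol_kg_d,
                     seed = cfg$seed)
write_exceedance_csv(rep_fw, "results/fieldworker_exceedance.csv")
print(rep_fw, digits = 3)
cat("true field-worker daily dose: 200 pmol/kg bw/d\n")
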