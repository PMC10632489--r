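#!/usr/bin/env Rscript
# MIRD absorbed doses and ICRP-103 effective doses for every subject and
# pipeline variant, against seeded synthetic sex-specific S-value tables
# (self-dose dominant, positive; no claim of agreement with any published
# phantom). Ends with the regulatory compliance check per administration.

suppressPackageStartupMessages(library(petdosim))

long <- read.csv("results/residence_times_long.csv")
scheme <- weighting_scheme("icrp103")
limits <- dose_limits()

organs <- setdiff(unique(long$organ), "remainder")
svals <- list(male = synthetic_svalue_table(organs, seed = 101),
              female = synthetic_svalue_table(organs, seed = 102,
                                              scale = 0.08 * 1.15))
write_svalue_file(svals$male, "results/svalues_male_synthetic.csv")
write_svalue_file(svals$female, "results/svalues_female_synthetic.csv")

as_rt <- function(d) {
  rt <- data.frame(organ = d$organ, tau_h = d$tau_h)
  attr(rt, "subject_id") <- d$subject[1]
  attr(rt, "sex") <- d$sex[1]
  class(rt) <- c("residence_table", "data.frame")
  rt
}

eff_rows <- list(); dose_rows <- list()
for (key in unique(paste(long$subject, long$method))) {
  d <- long[paste(long$subject, long$method) == key, ]
  rt <- as_rt(d)
  doses <- absorbed_doses(rt, svals[[d$sex[1]]])
  e <- suppressWarnings(effective_dose(doses, scheme))
  dose_rows[[key]] <- data.frame(subject = d$subject[1], sex = d$sex[1],
                                 method = d$method[1], organ = doses$organ,
                                 dose_uGy_per_MBq = doses$dose_uGy_per_MBq)
  eff_rows[[key]] <- data.frame(subject = d$subject[1], sex = d$sex[1],
                                method = d$method[1], E_uSv_per_MBq = e)
}
dose_long <- do.call(rbind, dose_rows)
eff <- do.call(rbind, eff_rows)
write.csv(dose_long, "results/absorbed_doses_long.csv", row.names = FALSE)
write.csv(eff, "results/effective_doses.csv", row.names = FALSE)

cat("mean effective dose (uSv/MBq) by cohort, sex and method:\n")
eff$cohort <- sub("_[mf]_[0-9]+$", "", eff$subject)
print(aggregate(E_uSv_per_MBq ~ cohort + sex + method, eff, mean), digits = 4)

# compliance: injected activities live in the TAC file headers
comp <- do.call(rbind, lapply(unique(eff$subject), function(id) {
  subj <- read_tac_file(file.path("results/subjects", paste0(id, ".csv")))
  e <- eff$E_uSv_per_MBq[eff$subject == id & eff$method == "conventional"]
  chk <- compliance_check(e, subj$injected_MBq, limits)
  data.frame(subject = id, injected_MBq = subj$injected_MBq,
             E_uSv_per_MBq = e, total_mSv = chk$total_mSv,
             pass_per_administration = chk$pass_per_administration,
             pass_per_year = chk$pass_per_year)
}))
write.csv(comp, "results/compliance.csv", row.names = FALSE)
cat(sprintf("\ncompliance: %d/%d subjects within %g mSv/administration (max %.2f mSv)\n",
            sum(comp$pass_per_administration), nrow(comp),
            limits$per_administration_mSv, max(comp$total_mSv)))
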