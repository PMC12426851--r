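# Independent symbolic oracles: the formulas re-expressed through logs and
# explicit component sums, so shared arithmetic mistakes cannot cancel.

egfr_oracle <- function(cr, age, female, black) {
  exp(log(175) - 1.154 * log(cr) - 0.203 * log(age) +
        ifelse(black, log(1.212), 0) + ifelse(female, log(0.742), 0))
}

lvm_oracle <- function(lvedd, ivsd, pwd) {
  s <- lvedd + ivsd + pwd
  0.832 * (s * s * s - lvedd * lvedd * lvedd) + 0.6
}

cha_oracle <- function(age, female, chf, htn, dm, stroke, vasc) {
  pts <- 0
  if (chf) pts <- pts + 1
  if (htn) pts <- pts + 1
  if (age >= 75) pts <- pts + 2 else if (age >= 65) pts <- pts + 1
  if (dm) pts <- pts + 1
  if (stroke) pts <- pts + 2
  if (vasc) pts <- pts + 1
  if (female) pts <- pts + 1
  pts
}

atria_age_table <- data.frame(
  lo = c(85, 75, 65, 0), hi = c(Inf, 85, 75, 65),
  no_stroke = c(6, 5, 3, 0), stroke = c(9, 7, 7, 8))

atria_oracle <- function(age, female, dm, chf, htn, prot, renal, stroke) {
  row <- which(age >= atria_age_table$lo & age < atria_age_table$hi)
  pts <- if (stroke) atria_age_table$stroke[row]
         else atria_age_table$no_stroke[row]
  pts + female + dm + chf + htn + prot + renal
}

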