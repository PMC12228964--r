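# All interpretation wording lives here so the plain-language layer can be
# audited in one place. Placeholders are filled by sprintf; every number comes
# from the report bundle's tables, nothing is recomputed at render time.

.report_templates <- list(
  model_intro = paste0(
    "A %s growth-curve model (degree-%d polynomial in %s, %s estimation) was ",
    "fitted to %d observations from %d individuals; %d incomplete rows were ",
    "excluded."),
  linear_up = paste0(
    "The linear %s term is positive (%s, 95%% CI %s to %s) and statistically ",
    "distinguishable from zero at the 95%% level: on average, %s scores ",
    "increase with %s near the centre of the data."),
  linear_down = paste0(
    "The linear %s term is negative (%s, 95%% CI %s to %s) and statistically ",
    "distinguishable from zero at the 95%% level: on average, %s scores ",
    "decrease with %s near the centre of the data."),
  linear_flat = paste0(
    "The linear %s term (%s, 95%% CI %s to %s) is not statistically ",
    "distinguishable from zero at the 95%% level: there is no clear average ",
    "linear trend in %s over %s."),
  nonlinear = paste0(
    "Higher-order polynomial terms are included, so the trajectory is ",
    "curved; single coefficients should not be read in isolation. The ",
    "predicted-score and area-under-curve summaries below describe the ",
    "fitted curve directly."),
  prediction = "At %s = %s, the predicted %s is %s (95%% CI %s to %s).",
  auc = paste0(
    "Between %s %s and %s, the area under the fitted trajectory is %s ",
    "(95%% CI %s to %s); this summarises the cumulative exposure to %s over ",
    "that period."),
  diff_clear = paste0(
    "At %s = %s, the difference in predicted %s between %s = %s and %s = %s ",
    "is %s (95%% CI %s to %s), a difference statistically distinguishable ",
    "from zero at the 95%% level."),
  diff_unclear = paste0(
    "At %s = %s, the difference in predicted %s between %s = %s and %s = %s ",
    "is %s (95%% CI %s to %s); the interval includes zero, so there is no ",
    "clear group difference at this %s."),
  auc_diff_clear = paste0(
    "Between %s %s and %s, the difference in area under the curve ",
    "(%s = %s minus %s = %s) is %s (95%% CI %s to %s), statistically ",
    "distinguishable from zero at the 95%% level."),
  auc_diff_unclear = paste0(
    "Between %s %s and %s, the difference in area under the curve ",
    "(%s = %s minus %s = %s) is %s (95%% CI %s to %s); the interval includes ",
    "zero, so there is no clear group difference in cumulative exposure."),
  singular_note = paste0(
    "Note: the fit is singular (an estimated random-effect variance is ",
    "zero); consider a simpler random-effects structure.")
)
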