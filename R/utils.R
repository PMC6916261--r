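# internal helpers shared across modules

inv_logit <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

# check scalar finite numeric
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

VEG_COLS <- c("veg_disturbed", "veg_moderate", "veg_undisturbed", "veg_mixed")
PATCH_TYPES <- c("papyrus", "shoreline", "broad_wetland")
CATEGORIES <- c("resistant_and_resilient", "resistant_only", "resilient_only",
                "marginal")
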