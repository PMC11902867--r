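Reference confusion matrices from the original clinical study (private
469-recording cohort): HMM predictions vs actual cord-pH class, for the
imbalanced train/test splits and the balanced (21 per class, 15 train / 6
test) splits. Rows = actual H1..H4, columns = predicted H1..H4. Used to
recompute the published per-class metrics and overall accuracies with
class_metrics().
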