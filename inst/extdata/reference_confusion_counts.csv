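disease,positives,true_positives,negatives,false_positives,reported_accuracy_pct,reported_sensitivity_pct,consistent,note
GLAU,2198,2115,6926,278,96.04,96,TRUE,
AMD,180,168,8944,110,98.66,93,TRUE,
RVO,411,394,873,99,98.73,96,FALSE,printed specificity 99.73% and accuracy 98.73% are not reproducible from these counts
DR,809,727,8315,251,96.35,90,TRUE,positive and true-positive counts appear transposed in the source narrative; this ordering reproduces the printed accuracy exactly
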