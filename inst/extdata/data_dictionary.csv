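file,column,description
scores.csv,rater,rater identifier (R1..Rn) or reference
scores.csv,view,anatomical view: anterior / superior / posterior / lateral_left / lateral_right
scores.csv,hemisphere,left / right / unassigned
scores.csv,label,canonical sulcus abbreviation after merging
scores.csv,dice,Dice overlap of the full-width drawing vs the reference pixels (0-1)
scores.csv,mmed,mean minimum Euclidean distance from the drawing centroid streamline to the reference pixels (pixels)
scores.csv,mmedn,normalized MMED: 1 - mmed/threshold below the saturation threshold and 0 at or beyond it
scores.csv,siss,similarity index for shape and spatial comparison: (dice + mmedn)/2
scores.csv,saturated,TRUE when mmed reached the saturation threshold (no spatial similarity)
scores.csv,corrected,TRUE when the row results from a label correction
table.csv,label,canonical sulcus abbreviation
table.csv,<view>_<hemisphere>,mean SISS over the raters who drew that cell; - when nobody did
table.csv,average_left/average_right,mean over the present view cells of that hemisphere (absent cells skipped)
rates.csv,n_raters,number of distinct raters who drew the sulcus in the view
rates.csv,rate,n_raters divided by the full cohort size
zones.csv,zone,green: mean SISS > 0.5 with > 20% of raters in at least one view; yellow: best qualifying view in (0.4 0.5]; red: otherwise
zones.csv,best_view_siss,mean SISS of the best view with sufficient identification rate (best overall when none qualifies)
zones.csv,best_view_rate,highest identification rate across views
corrections.csv,drawn_label,label under which the stroke was drawn
corrections.csv,corrected_labels,true label(s) semicolon-separated; NONE when the drawing matches no real sulcus
truth_log.csv,true_label,reference sulcus the simulated stroke was generated from
truth_log.csv,drawn_label,label the simulated rater attached (may differ after a mislabel swap)
truth_log.csv,omitted,TRUE when the rater did not draw this sulcus
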