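trial,total_plants,actual_mutants,predicted_mutants,correctly_predicted,prediction_errors,undetected,printed_accuracy,printed_fpr,printed_fnr
1,102,8,14,7,7,1,0.875,0.069,0.125
2,108,14,11,6,5,8,0.429,0.046,0.571
3,102,8,13,5,8,3,0.625,0.058,0.375
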