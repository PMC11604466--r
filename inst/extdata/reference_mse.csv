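dataset,model,benchmark_mse,validation_mse
1,traditional_gcn,0.0111,0.0103
1,traditional_sage,0.0116,0.0104
1,line_gcn,0.0115,0.0099
1,line_sage,0.0122,0.0085
2,traditional_gcn,0.0271,0.0270
2,traditional_sage,0.0273,0.0250
2,line_gcn,0.0418,0.0183
2,line_sage,0.0329,0.0187
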