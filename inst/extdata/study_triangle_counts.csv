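visit,n_triangles,pct_connected
2,16330,66
3,14235,66
4,12018,67
5,9865,71
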