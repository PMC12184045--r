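a_score,b_score,c_score,level
0,0,0,not
0,0,1,not
0,0,2,not
0,0,3,not
0,1,0,not
0,1,1,not
0,1,2,not
0,1,3,not
0,2,0,not
0,2,1,not
0,2,2,not
0,2,3,not
0,3,0,not
0,3,1,not
0,3,2,not
0,3,3,not
1,0,0,low
1,0,1,low
1,0,2,low
1,0,3,low
1,1,0,low
1,1,1,low
1,1,2,low
1,1,3,low
1,2,0,low
1,2,1,low
1,2,2,intermediate
1,2,3,intermediate
1,3,0,low
1,3,1,low
1,3,2,intermediate
1,3,3,intermediate
2,0,0,low
2,0,1,low
2,0,2,low
2,0,3,low
2,1,0,low
2,1,1,low
2,1,2,low
2,1,3,low
2,2,0,intermediate
2,2,1,intermediate
2,2,2,intermediate
2,2,3,intermediate
2,3,0,intermediate
2,3,1,intermediate
2,3,2,intermediate
2,3,3,intermediate
3,0,0,low
3,0,1,low
3,0,2,low
3,0,3,low
3,1,0,low
3,1,1,low
3,1,2,low
3,1,3,low
3,2,0,intermediate
3,2,1,intermediate
3,2,2,intermediate
3,2,3,intermediate
3,3,0,intermediate
3,3,1,intermediate
3,3,2,high
3,3,3,high
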