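expert,class_id,value
1,1,0
2,1,0
3,1,0
4,1,0
5,1,0
6,1,0
1,2,35
2,2,40
3,2,40
4,2,40
5,2,40
6,2,45
1,3,55
2,3,60
3,3,60
4,3,60
5,3,60
6,3,65
1,4,90
2,4,95
3,4,95
4,4,95
5,4,95
6,4,100
1,5,75
2,5,80
3,5,80
4,5,80
5,5,80
6,5,85
1,6,55
2,6,60
3,6,60
4,6,60
5,6,60
6,6,65
1,7,0
2,7,0
3,7,0
4,7,0
5,7,0
6,7,0
1,8,55
2,8,60
3,8,60
4,8,60
5,8,60
6,8,65
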