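food,group,grams,carbohydrate_g_100g,fiber_g_100g,fat_g_100g,sfa_g_100g,protein_g_100g,sodium_mg_100g
oat flakes,cereals,60,58,10,7,1.3,13,5
wholemeal couscous,cereals,180,23,2.9,0.6,0.1,6,5
olive oil,fats and oils,28,0,0,100,14,0,0
fresh cheese,milk and dairy products,80,3.5,0,11,7.2,12,300
plain yogurt,milk and dairy products,125,5,0,3.3,2.1,4,60
fruit jam,"sugars, sweets and pastries",20,60,0.8,0.1,0,0.4,10
red wine (dealc.),beverages,100,3,0,0,0,0.1,4
rabbit stew,meat and meat products,110,0,0,5.5,1.8,21,65
pear,fruits and nuts,180,12,3.1,0.1,0,0.4,1
hazelnuts,fruits and nuts,20,7,9.7,61,4.5,15,0
white beans (cooked),legumes,180,16,6.3,0.6,0.1,8,6
grilled salmon,fish,100,0,0,12,2.5,20,60
roasted peppers,vegetables,250,6,2.1,0.3,0,1,20
hummus,miscellaneous,40,14,5.4,10,1.3,7,240
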