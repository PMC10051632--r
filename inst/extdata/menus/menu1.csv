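food,group,grams,carbohydrate_g_100g,fiber_g_100g,fat_g_100g,sfa_g_100g,protein_g_100g,sodium_mg_100g
whole-grain bread,cereals,140,41,7,3.5,0.7,9,430
cooked pasta,cereals,160,28,2.5,1.5,0.3,5.5,5
olive oil,fats and oils,25,0,0,100,14,0,0
plain yogurt,milk and dairy products,250,5,0,3.3,2.1,4,60
honey,"sugars, sweets and pastries",15,80,0,0,0,0.4,4
orange juice,beverages,200,9,0.2,0.2,0,0.7,1
chicken breast,meat and meat products,100,0,0,2.5,0.7,23,70
apple,fruits and nuts,200,12,2.4,0.2,0,0.3,1
almonds,fruits and nuts,25,6,12.5,50,3.8,21,1
boiled egg,eggs,50,0.7,0,10,3,12.5,140
grilled hake,fish,120,0,0,2,0.4,17,100
cooked chickpeas,legumes,150,20,7.5,2.5,0.3,8,5
mixed vegetables,vegetables,300,5,2.5,0.3,0.1,1.5,30
tomato sauce,miscellaneous,30,8,1.5,4,0.6,1.5,400
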